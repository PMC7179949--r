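---
title: "Atlas-localized semi-NMF for widefield calcium imaging: models and methods"
author: "locanmf package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-localized semi-NMF: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locanmf)
```

# The decomposition problem

Widefield calcium imaging records fluorescence over the dorsal cortex at
tens of micrometers per pixel and tens of frames per second. After
denoising, hemodynamic correction and dF/F conversion, the video is a
pixels-by-time matrix $Y \in \mathbb{R}^{N \times T}$ that we want to demix
into a small number of interpretable signals,

$$ Y \approx A\,C, \qquad A \ge 0,\ \lVert a_k \rVert_\infty = 1, $$

with nonnegative spatial components $A = [a_1, \dots, a_K]$ (indicator
density per pixel) and sign-unconstrained temporal components
$C \in \mathbb{R}^{K \times T}$ (dF/F can be negative). Unconstrained
semi-NMF, like PCA, returns spatially delocalized components that are hard
to compare across sessions and animals. This package therefore anchors
every component to a region of a user-supplied brain atlas — any integer
label image partitioning the field of view into $J$ disjoint regions
$\pi_1, \dots, \pi_J$ — and penalizes spatial mass far from the component's
home region:

$$ \sum_n \lvert d_k(n)\, a_k(n) \rvert^2 \le L_k, $$

where $d_k(n)$ is the smallest Euclidean distance (in pixel units) from
pixel $n$ to the region assigned to component $k$ (zero inside). The
constraints are enforced softly through per-component Lagrange multipliers
$\lambda_k$, which are never set by the user: they are tuned automatically
from two interpretable thresholds described below.

Pixel bookkeeping: pixels labeled 0 lie outside the field of view and are
excluded everywhere; in-FOV pixels are enumerated row-major; pixel centers
sit at integer coordinates. The distance fields are exact Euclidean
distance transforms (verified against brute force in the test suite), one
column per region; components of the same region share a column.

# Everything happens in a low-rank temporal subspace

The input video arrives (or is put by `truncatedSVD()`) in factored form
$Y = U V$ with $U \in \mathbb{R}^{N \times K_d}$,
$V \in \mathbb{R}^{K_d \times T}$, $K_d \ll T$. An LQ decomposition
$V = L\,Q$ ($L$ lower-triangular $K_d \times K_d$, $Q$ with orthonormal
rows; computed as the transpose of an unpivoted Householder QR of $V^\top$,
with a modified Gram–Schmidt fallback for rank-deficient inputs, and signs
fixed so $\operatorname{diag}(L) \ge 0$) turns every residual computation
into subspace arithmetic: writing $C = B\,Q$,

$$ \lVert U V - A C \rVert_F = \lVert U L - A B \rVert_F, $$

so the algorithm only ever touches $U$ and $L$; $Q$ is needed once at the
end to materialize $C$. This is what makes hour-long recordings tractable:
cost scales with $N K_d K$ rather than $N T K$.

# Fitting: hierarchical alternating least squares

`halsSpatial()` and `halsTemporal()` implement block coordinate descent,
one component at a time, each update using the already-updated columns:

* spatial: $a_k \leftarrow \big[a_k + \big((U L B^\top)_k - (A B
  B^\top)_k - \lambda_k d_k\big) / \lVert b_k \rVert^2\big]_+$
* normalize: each nonzero $a_k$ is divided by its maximum and the factor
  multiplied into $b_k$ (so $\lVert a_k \rVert_\infty = 1$ and $A B$ is
  unchanged)
* temporal: $b_k \leftarrow b_k + \big((A^\top U)_k L - (A^\top A)_k
  B\big) / \lVert a_k \rVert^2$

The spatial divisor is $\lVert b_k \rVert^2 = c_k^\top c_k$ (the two agree
because $Q Q^\top = I$). Components whose divisor is numerically zero are
skipped; columns that become identically zero are pruned at phase
boundaries (with the per-region counts decremented) so no dead component
ever divides by zero. With $\lambda = 0$ each update is an exact coordinate
minimizer, so the unpenalized objective is non-increasing sweep after sweep
(a property the test suite checks on random instances). With
$\lambda_k > 0$ the spatial step minimizes the *penalized* objective; the
recorded `objectiveTrace` reports the plain squared error, which in
practice still decreases but is not mathematically guaranteed to.

# The two user-facing thresholds and the nested search

The two hyperparameter families — per-region component counts
$k_1, \dots, k_J$ and multipliers $\lambda_1, \dots, \lambda_K$ — are tuned
by `locaNMF()` from

* `r2Thr` (default 0.99): minimum acceptable per-region variance explained
  $$ R^2(j) = 1 - \frac{1}{|\pi_j|} \sum_{n \in \pi_j}
     \frac{\lVert U(n)L - A(n)B \rVert^2}{\text{temporal variance of pixel } n}, $$
  where the denominator is evaluated in the subspace as
  $\lVert U(n)L\rVert^2 - T\,(U(n)L\bar q)^2$ with $\bar q = Q\mathbf{1}/T$
  — exactly the time-domain sum of squared deviations from the pixel's
  temporal mean. Pixels with variance below $10^{-12}$ (dead pixels) are
  excluded from the average; a region with no live pixels reports
  $R^2 = 1$ with a warning.
* `locThr` (default 0.80; 0.70 in the simulation benchmark): minimum
  localization $L(k) = \sum_{n \in \phi(k)} a_k(n)^2 / \lVert a_k
  \rVert^2$, the fraction of squared spatial mass inside the component's
  own region.

The search is nested. The outer loop starts at `kMin` components per
region and, after each converged inner loop, increments the count of every
region with $R^2(j)$ below threshold, re-initializing all components from
cached per-region SVDs (no warm start across rank proposals; within the
inner loop, successive $\lambda$ proposals do warm-start). The inner loop
starts all multipliers at a common floor and, after each HALS phase
(`maxitersHals` sweeps of spatial → normalize → temporal), multiplies by
`tauStep` (default 1.25) the multiplier of every component whose
localization is below threshold, stopping when all components pass. Both
loops return the best fit so far with convergence flags (never an error)
when their iteration caps are hit. Components are reported ordered by
(region, decreasing temporal energy), making the output deterministic.

## Choosing the multiplier floor

The floor matters more than it looks. In the spatial update the penalty
entries $\lambda_k d_k(n)$ compete with gradient entries of size
$\lvert (U L B^\top)_{nk} \rvert$, so

$$ S = \frac{\max \lvert U L B^\top \rvert}{\operatorname{median}\{d > 0\}} $$

is the scale at which the penalty saturates (out-of-region pixels are
clipped to zero in one update). The floor is `lambdaMin` $\times\, S$ with
`lambdaMin` = 1e-3: small enough that the first model is essentially
unconstrained (the paper-style "least constrained to most constrained"
progression is preserved), large enough that the multiplicative search
reaches the active regime within a few dozen steps and the atlas-based
initialization is not washed out by effectively-unpenalized sweeps in the
meantime. Two failure modes motivated this choice and are worth recording:
with a floor many orders of magnitude below $S$, either (a) the inner loop
exhausts its budget before $\lambda$ reaches the active regime and
localization fails, or (b) with a large budget, the long unconstrained
phase converges to the delocalized semi-NMF optimum, a region's only
component dies, and the rank search oscillates. Because both $S$ and the
update scale as the squared data amplitude, the search is invariant to
rescaling the video. `maxitersLambda` defaults to 100 so the
multiplicative ladder ($1.25^{99} \approx 4 \times 10^9$) can cover the
full range; components stop moving individually as soon as they pass.

## Initialization

For each region independently, `initSNMF()` takes the top-$k_j$ temporal
directions of a precomputed rank-`kMax` SVD of the region-restricted
subspace data $U_{\pi_j} L$ (scaled by singular values; signs canonicalized
through the left singular vectors so the result does not depend on how the
temporal subspace is represented), sets the spatial columns to ones on the
region's pixels, and runs unpenalized HALS confined to the region. The
per-region SVDs are computed once and reused by every rank proposal. This
initialization is fully deterministic — repeated runs give identical fits,
in contrast to the Bernoulli-initialized `vanillaNMF()` baseline, whose
run-to-run variability the test suite demonstrates.

# The vanilla baseline

`vanillaNMF()` is unlocalized semi-NMF: each spatial column starts as an
independent Bernoulli(0.1) pixel mask (redrawn, boundedly, if empty), each
temporal component as the mean trace of its masked pixels, followed by
alternating [normalize temporal rows, spatial HALS, temporal HALS] sweeps
with no penalty, all in the same subspace. It is seeded and reproducible
per seed, and deliberately kept initialization-dependent across seeds — it
exists to quantify what the localization machinery buys.

# Hemodynamic correction and dF/F, in factored form

For dual-channel recordings (activity channel $Y_g = U_g V_g$, blood-flow
reference $Y_h = U_h V_h$), `fitHemodynamics()` low-passes the reference
temporal factor (2nd-order Butterworth, default cutoff 15 Hz, applied
forward and backward so no lag enters the regression; implemented with
odd-extension padding and steady-state initial conditions so DC gain is
exactly 1) and fits per pixel $y_i(t) = b_i x_i(t) + t_i$ by least squares,
accumulating all sufficient statistics in the subspace. Pixels whose
filtered reference has zero variance fall back to $b = 0$, $t =$ pixel
mean. `applyCorrection()` assembles the residual without densifying:
$U \leftarrow [U_g,\ -\operatorname{diag}(b) U_h,\ t]$,
$V \leftarrow [V_g;\ V_h^{\mathrm{lpf}};\ \mathbf{1}]$, so the
reconstruction is $Y_g - \operatorname{diag}(b) Y_h^{\mathrm{lpf}} + t$ —
the intercept is carried with a plus sign, exactly as the stacked factors
dictate; whether it belongs in the corrected signal is moot because the
mean adjustment of `dff()` removes any constant. `dff()` maps every trace
to $(F - \bar F)/\bar F$ by row-rescaling $U$ and appending one constant
component; pixels with $\lvert \bar F \rvert \le$ `epsF` cannot be
normalized and are zeroed with a report. A note on the rank bookkeeping:
stacked representations carry $K_d(g) + K_d(h) + 1$ columns, which may
exceed the matrix rank (and even $N$ on toy problems) — the container only
requires $K_d \le T$, which is what the LQ split needs.

# The synthetic benchmark

`makeSyntheticAtlas()` draws $J$ seed pixels uniformly and labels each grid
pixel by its nearest seed (Euclidean, ties to the lowest seed index) —
convex, connected, nonempty regions standing in for an aligned cortical
atlas. `simulateSpatial()` plants one component per region: an isotropic
Gaussian centered at the per-coordinate median of the region's pixels with
$\sigma_j = 0.2 \sqrt{|\pi_j|}$ (proportional to the region's linear size),
evaluated over the whole image and peak-normalized — so planted components
genuinely overlap neighboring regions, which is what makes localization
non-trivial. `simulateTemporal()` draws a pool of ten angular frequencies
$\beta' \sim U(0.5, 0.63)$ and builds each trace as three sinusoids with
amplitudes $\alpha \sim U(-1.5, 1.5)$ and frequencies drawn with
replacement from the pool, plus Gaussian noise of sd 0.1; time is indexed
in frame units (at the 30 Hz default these are 2.4–3 Hz oscillations), with
10,000 frames by default. `simulateDataset()` returns the video directly in
factored form ($U = A_{\text{real}}$, $V = C_{\text{real}}$, rank $= J$),
plus the ground truth. All generators are pure functions of their seed and
restore the caller's RNG state.

The default benchmark used throughout the tests and the acceptance script
is a 64×64 grid with $J = 10$ regions and $T = 10{,}000$ frames — large
enough that the subspace machinery is exercised meaningfully, small enough
for a desk-scale run (the full search converges in seconds). What passing
on this benchmark shows — and what it does not: the generator emulates the
region-anchored, spatially overlapping, temporally correlated structure of
widefield data, but it is exactly low-rank, noise lives only in the traces,
regions are convex, and there is no motion, vignetting, or hemodynamic
contamination unless the paired channel is requested. Threshold attainment
and planted-factor recovery on it validate the algorithm, not the
biology of any particular preparation.

# Cross-session comparison

`matchComponents()` pairs components of two fits greedily by cosine
similarity (correlation optionally), highest remaining pair first, ties to
the lowest index, zero columns matching nothing with similarity 0.
`ccaMap()` summarizes inter-region temporal structure as the first
canonical correlation between the component sets of every region pair —
components are mean-centered over time, within-region covariances get a
ridge of 1e-8 to tolerate rank deficiency, and the whitened cross-
covariance's top singular value is clipped to $[0, 1]$. `mapDistance()`
compares two such maps by the mean squared difference over off-diagonal
upper-triangle entries.

# Numerical choices, degenerate inputs, limitations

* Tolerances: LQ reconstruction and orthonormality are held to 1e-8
  (relative); dead-pixel and dead-component guards use 1e-12; subspace
  computations match dense brute force to 1e-6 relative on 50×50×500
  instances in the acceptance tests.
* Degenerate inputs: an all-zero video returns the trivial fit
  ($J \cdot$`kMin` components, zero mixing, $R^2$ reported 1 through the
  guard path) in a single outer iteration; all-zero regions, empty
  Bernoulli masks and constant reference channels are all handled
  explicitly.
* The per-region SVD cap `kMax` (default 16) bounds both the
  initialization rank and the per-region component count; requests beyond
  a region's pixel count are clamped with a warning.
* Limitations: no motion correction and no atlas alignment (inputs are
  assumed registered to the label image); 2-D atlases only; the
  multiplicative $\lambda$ ladder finds the *smallest localizing
  multiplier up to a factor of* `tauStep`, not the exact minimum; no
  decimation or GPU path — the backend contract (all heavy operations
  defined on $U, L, A, B$ with fixed post-conditions) is what an
  accelerated drop-in would have to satisfy.
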