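#' Configuration for the adaptive LocaNMF search
#'
#' The two scientific knobs are \code{r2Thr} (minimum acceptable per-region
#' variance explained, driving the per-region component counts) and
#' \code{locThr} (minimum fraction of each component's squared spatial mass
#' that must lie inside its own atlas region, driving the penalty
#' multipliers). The remaining entries control the nested search:
#' \code{lambdaMin} is relative to the data scale (median |U L|) so the
#' search behaves identically under rescaling of the input; \code{tauStep}
#' is the multiplicative lambda step (1 + epsilon).
#'
#' @param r2Thr minimum region R-squared in (0, 1]; default 0.99.
#' @param locThr minimum localization fraction in (0, 1]; default 0.80.
#' @param kMin starting per-region component count (>= 1); default 1.
#' @param kMax per-region rank of the precomputed initialization SVDs and
#'   cap on per-region components; default 16.
#' @param lambdaMin initial penalty multiplier relative to data scale;
#'   default 1e-6.
#' @param tauStep multiplicative lambda increase (> 1); default 1.25.
#' @param maxitersK outer iterations over component-count proposals;
#'   default 30.
#' @param maxitersLambda lambda proposals per component-count proposal;
#'   default 100 (the multiplicative search must be able to traverse the
#'   six orders of magnitude between a negligible and a saturating penalty:
#'   1.25^99 is about 4e9, and components stop moving individually as soon
#'   as they are localized).
#' @param maxitersHals HALS sweeps per lambda proposal; default 30.
#' @param rngSeed seed recorded with the fit (the fit itself is
#'   deterministic: initialization is SVD-based).
#' @return a validated list of class \code{LocaNMFConfig}
#' @export
locaNMFConfig <- function(r2Thr = 0.99, locThr = 0.80, kMin = 1L, kMax = 16L,
                          lambdaMin = 1e-3, tauStep = 1.25, maxitersK = 30L,
                          maxitersLambda = 100L, maxitersHals = 30L,
                          rngSeed = 1L) {
  stopifnot(r2Thr > 0, r2Thr <= 1, locThr > 0, locThr <= 1,
            kMin >= 1, kMax >= kMin, lambdaMin > 0, tauStep > 1,
            maxitersK >= 1, maxitersLambda >= 1, maxitersHals >= 1)
  structure(list(r2Thr = r2Thr, locThr = locThr, kMin = as.integer(kMin),
                 kMax = as.integer(kMax), lambdaMin = lambdaMin,
                 tauStep = tauStep, maxitersK = as.integer(maxitersK),
                 maxitersLambda = as.integer(maxitersLambda),
                 maxitersHals = as.integer(maxitersHals),
                 rngSeed = as.integer(rngSeed)),
            class = "LocaNMFConfig")
}

#' Per-region variance explained (region R-squared)
#'
#' For each atlas region, one minus the average over the region's pixels of
#' the ratio between the squared reconstruction error of the pixel's trace
#' and the pixel's temporal variance, evaluated entirely in the LQ subspace
#' (||U(n) L - A(n) B||^2 equals the dense time-domain error). Pixels with
#' numerically zero temporal variance are excluded from the average; a
#' region whose pixels are all excluded reports 1 with a warning (nothing to
#' explain).
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}}.
#' @param A,B fitted spatial components and subspace mixing.
#' @param atlas the \code{\linkS4class{Atlas}}.
#' @param vt optional precomputed \code{\link{pixelVarianceTerms}}.
#' @return numeric vector of length J
#' @export
regionR2 <- function(lrv, A, B, atlas, vt = NULL) {
  if (is.null(vt)) vt <- pixelVarianceTerms(lrv)
  err <- rowSums((vt$UL - A %*% B)^2)
  ratio <- ifelse(vt$keep, err / ifelse(vt$keep, vt$denom, 1), NA_real_)
  J <- nRegions(atlas)
  out <- numeric(J)
  for (j in seq_len(J)) {
    sel <- atlas@pixelRegion == j & vt$keep
    if (!any(sel)) {
      warning("region ", atlas@regionIds[j],
              ": all pixels have zero temporal variance; R2 reported as 1")
      out[j] <- 1
    } else out[j] <- 1 - mean(ratio[sel])
  }
  out
}

#' Localization score of spatial components
#'
#' Fraction of each component's squared spatial mass that lies inside its
#' own atlas region: L(k) = sum_{n in region(k)} a_k(n)^2 / ||a_k||^2, in
#' [0, 1]. An identically-zero component is vacuously localized (score 1)
#' and flagged by attribute \code{"zero"}.
#'
#' @param A spatial components (N x K).
#' @param phi integer vector, internal region index of each component.
#' @param atlas the \code{\linkS4class{Atlas}}.
#' @return numeric vector of length K with attribute \code{"zero"}
#' @export
localizationScore <- function(A, phi, atlas) {
  K <- ncol(A)
  tot <- colSums(A^2)
  zero <- tot <= 0
  out <- numeric(K)
  for (k in seq_len(K)) {
    if (zero[k]) { out[k] <- 1; next }
    sel <- atlas@pixelRegion == phi[k]
    out[k] <- sum(A[sel, k]^2) / tot[k]
  }
  attr(out, "zero") <- zero
  out
}

# Precompute, per region, the SVD of the region-restricted subspace data
# U[pixels_j, ] %*% L up to rank kMax; reused by every initialization phase.
precomputeRegionSVD <- function(U, L, atlas, kMax) {
  pix <- regionPixels(atlas)
  lapply(pix, function(idx) {
    M <- U[idx, , drop = FALSE] %*% L
    r <- min(kMax, nrow(M), ncol(M))
    sv <- svd(M, nu = r, nv = r)
    # canonical signs via the left singular vectors (pixel space), which do
    # not depend on how the temporal subspace is represented
    for (i in seq_len(r)) {
      s <- sum(sv$u[, i])
      if (s < 0 || (s == 0 && sum(sv$v[, i]) < 0)) {
        sv$v[, i] <- -sv$v[, i]
        sv$u[, i] <- -sv$u[, i]
      }
    }
    list(d = sv$d[seq_len(r)], v = sv$v, pixels = idx)
  })
}

#' Semi-NMF initialization of the localized factorization
#'
#' Initializes the components of every region independently: the region's
#' mixing rows start from the top temporal directions of the precomputed
#' within-region SVD of U_j L (scaled by their singular values), the spatial
#' columns start as ones on the region's pixels (zero elsewhere), and
#' \code{maxitersHals} unpenalized HALS sweeps are run confined to the
#' region's pixels. The assembled A is block-structured: at initialization
#' each component's support is inside its region.
#'
#' @param U,L low-rank video factors.
#' @param atlas the \code{\linkS4class{Atlas}}.
#' @param ranks integer vector (length J) of per-region component counts;
#'   entries exceeding the region's pixel count are clamped with a warning.
#' @param maxitersHals HALS sweeps per region.
#' @param svdCache optional output of the internal per-region SVD
#'   precomputation (recomputed when NULL).
#' @param kMax rank of the precomputed SVDs when \code{svdCache} is NULL.
#' @return list with \code{A} (N x K), \code{B} (K x Kd), \code{phi}
#'   (length K) and the clamped \code{ranks}
#' @export
initSNMF <- function(U, L, atlas, ranks, maxitersHals = 30L,
                     svdCache = NULL, kMax = max(ranks)) {
  J <- nRegions(atlas)
  stopifnot(length(ranks) == J)
  if (any(ranks < 1)) stop("per-region component counts must be >= 1")
  if (is.null(svdCache)) svdCache <- precomputeRegionSVD(U, L, atlas, kMax)
  N <- nrow(U); Kd <- ncol(L)

  Ablocks <- vector("list", J); Bblocks <- vector("list", J)
  ranks <- as.integer(ranks)
  for (j in seq_len(J)) {
    sv <- svdCache[[j]]
    idx <- sv$pixels
    kj <- ranks[j]
    avail <- length(sv$d)
    if (kj > avail) {
      warning("region ", atlas@regionIds[j], ": requested ", kj,
              " components but only ", avail, " available; clamping")
      kj <- avail
      ranks[j] <- kj
    }
    # top-kj temporal directions of the within-region SVD of U_j L
    Bj <- t(sv$v[, seq_len(kj), drop = FALSE]) * sv$d[seq_len(kj)]
    Aj <- matrix(1, length(idx), kj)
    Uj <- U[idx, , drop = FALSE]
    for (it in seq_len(maxitersHals)) {
      Aj <- halsSpatial(Uj, L, Aj, Bj)
      nc <- normalizeComponents(Aj, Bj)
      Aj <- nc$A; Bj <- nc$B
      Bj <- halsTemporal(Uj, L, Aj, Bj)
    }
    Afull <- matrix(0, N, kj)
    Afull[idx, ] <- Aj
    Ablocks[[j]] <- Afull
    Bblocks[[j]] <- Bj
  }
  list(A = do.call(cbind, Ablocks), B = do.call(rbind, Bblocks),
       phi = rep(seq_len(J), ranks), ranks = ranks)
}

# Drop identically-zero components; returns updated state.
pruneComponents <- function(A, B, phi, lambdas) {
  zero <- apply(A, 2L, max) <= 0
  if (any(zero)) {
    keep <- !zero
    A <- A[, keep, drop = FALSE]
    B <- B[keep, , drop = FALSE]
    phi <- phi[keep]
    lambdas <- lambdas[keep]
  }
  list(A = A, B = B, phi = phi, lambdas = lambdas, pruned = sum(zero))
}

#' Localized semi-NMF of a widefield video (LocaNMF)
#'
#' Fits the atlas-localized semi-NMF by a nested adaptive search. The outer
#' loop proposes per-region component counts, starting at \code{kMin}
#' everywhere and incrementing the count of every region whose R-squared is
#' below \code{r2Thr}; each proposal is (re)initialized from cached
#' within-region SVDs via \code{\link{initSNMF}}. The inner loop proposes
#' penalty multipliers, starting at the scale-relative \code{lambdaMin} and
#' multiplying by \code{tauStep} the multiplier of every component whose
#' localization score is below \code{locThr}; each proposal runs
#' \code{maxitersHals} sweeps of [penalized spatial update, max-normalize,
#' temporal update], warm-starting from the previous lambda iterate. The
#' inner loop stops when all components are localized, the outer loop when
#' all regions are explained. Non-convergence at the iteration caps returns
#' the best fit so far with convergence flags in the diagnostics rather
#' than an error. The procedure is deterministic for fixed inputs.
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}} (LQ computed if absent).
#' @param atlas the \code{\linkS4class{Atlas}} sharing the pixel indexing.
#' @param config a \code{\link{locaNMFConfig}}.
#' @param verbose print one line per (rank, lambda) proposal.
#' @return a \code{\linkS4class{LocaNMFFit}}
#' @export
locaNMF <- function(lrv, atlas, config = locaNMFConfig(), verbose = FALSE) {
  stopifnot(is(lrv, "LowRankVideo"), is(atlas, "Atlas"),
            inherits(config, "LocaNMFConfig"))
  if (nPixels(lrv) != nPixels(atlas))
    stop("video has ", nPixels(lrv), " pixels but atlas has ", nPixels(atlas))
  lrv <- ensureLQ(lrv)
  U <- lrv@U; L <- lrv@L
  J <- nRegions(atlas)
  Dfields <- distanceFields(atlas)
  vt <- pixelVarianceTerms(lrv)
  svdCache <- precomputeRegionSVD(U, L, atlas, config$kMax)
  regionSize <- tabulate(atlas@pixelRegion, nbins = J)

  ranks <- pmin(rep(config$kMin, J), regionSize)
  lambdaFloor <- NULL  # set from the first initialization below
  objTrace <- numeric(0)
  itersK <- 0L; totalLambdaIters <- 0L; totalHalsIters <- 0L
  convergedR2 <- FALSE; convergedLoc <- FALSE
  A <- B <- NULL; phi <- integer(0); lambdas <- numeric(0)
  r2 <- rep(NA_real_, J); loc <- numeric(0)

  for (iterK in seq_len(config$maxitersK)) {
    itersK <- iterK
    init <- initSNMF(U, L, atlas, ranks, config$maxitersHals,
                     svdCache = svdCache, kMax = config$kMax)
    A <- init$A; B <- init$B; phi <- init$phi; ranks <- init$ranks
    if (is.null(lambdaFloor)) {
      # Scale-relative lambda floor. In the spatial update the penalty
      # entries lambda d_nk compete with the gradient entries (U L B')_nk,
      # so their ratio fixes the natural lambda unit: lambda of order
      # S = max|U L B'| / median positive distance saturates the penalty
      # (out-of-region pixels are clipped to zero). The floor starts the
      # search at lambdaMin * S -- small enough that the first model is
      # essentially unconstrained, large enough that the multiplicative
      # search reaches the active regime within a few dozen steps and the
      # atlas-based initialization is not forgotten in the meantime. Both
      # S and the update scale as the squared data amplitude, so the whole
      # search is invariant to rescaling the input video.
      num <- max(abs(U %*% tcrossprod(L, B)))
      den <- stats::median(Dfields[Dfields > 0])
      lambdaFloor <- config$lambdaMin * max(num, .Machine$double.eps) /
        max(den, 1)
    }
    lambdas <- rep(lambdaFloor, length(phi))
    Dcols <- Dfields[, phi, drop = FALSE]

    convergedLoc <- FALSE
    for (iterL in seq_len(config$maxitersLambda)) {
      totalLambdaIters <- totalLambdaIters + 1L
      for (it in seq_len(config$maxitersHals)) {
        A <- halsSpatial(U, L, A, B, lambdas, Dcols)
        nc <- normalizeComponents(A, B)
        A <- nc$A; B <- nc$B
        B <- halsTemporal(U, L, A, B)
        objTrace <- c(objTrace, halsObjective(U, L, A, B))
        totalHalsIters <- totalHalsIters + 1L
      }
      pr <- pruneComponents(A, B, phi, lambdas)
      if (pr$pruned > 0) {
        A <- pr$A; B <- pr$B; phi <- pr$phi; lambdas <- pr$lambdas
        ranks <- tabulate(phi, nbins = J)
        Dcols <- Dfields[, phi, drop = FALSE]
      }
      loc <- localizationScore(A, phi, atlas)
      if (verbose)
        message(sprintf("k-iter %d lambda-iter %d: K=%d minLoc=%.3f",
                        iterK, iterL, length(phi), min(loc)))
      if (all(loc >= config$locThr)) { convergedLoc <- TRUE; break }
      bump <- loc < config$locThr
      lambdas[bump] <- lambdas[bump] * config$tauStep
    }

    r2 <- regionR2(lrv, A, B, atlas, vt = vt)
    if (verbose)
      message(sprintf("k-iter %d: ranks=[%s] minR2=%.4f", iterK,
                      paste(ranks, collapse = ","), min(r2)))
    if (all(r2 >= config$r2Thr)) { convergedR2 <- TRUE; break }
    grow <- r2 < config$r2Thr
    ranks <- pmin(ranks + as.integer(grow), regionSize, config$kMax)
  }

  # deterministic ordering: by region, then decreasing temporal energy
  bnorm <- sqrt(rowSums(B^2))
  ord <- order(phi, -bnorm)
  A <- A[, ord, drop = FALSE]
  B <- B[ord, , drop = FALSE]
  phi <- phi[ord]; lambdas <- lambdas[ord]
  loc <- localizationScore(A, phi, atlas)

  diag <- list(
    r2ByRegion = r2,
    locByComponent = as.numeric(loc),
    objectiveTrace = objTrace,
    itersUsed = list(K = itersK, lambda = totalLambdaIters,
                     hals = totalHalsIters),
    converged = list(r2 = convergedR2, localization = convergedLoc),
    config = config
  )
  new(Class = "LocaNMFFit", A = A, B = B, C = B %*% lrv@Q,
      phi = as.integer(phi), lambdas = lambdas,
      ranks = as.integer(tabulate(phi, nbins = J)),
      regionIds = regionIds(atlas), diagnostics = diag)
}

#' @describeIn spatialComponents spatial factor of a fit
#' @export
setMethod("spatialComponents", "SemiNMFFit", function(x) x@A)

#' @describeIn temporalComponents temporal factor of a fit
#' @export
setMethod("temporalComponents", "SemiNMFFit", function(x) x@C)

#' @describeIn mixingWeights subspace mixing of a fit
#' @export
setMethod("mixingWeights", "SemiNMFFit", function(x) x@B)

#' @describeIn reconstruct dense N x T product A C of a fit
#' @export
setMethod("reconstruct", "SemiNMFFit", function(x) x@A %*% x@C)

#' @describeIn nTimepoints frames of a fit
#' @export
setMethod("nTimepoints", "SemiNMFFit", function(x) ncol(x@C))

#' @describeIn componentRegions region index of each component
#' @export
setMethod("componentRegions", "LocaNMFFit", function(x) x@phi)

#' @describeIn regionIds region labels of a fit
#' @export
setMethod("regionIds", "LocaNMFFit", function(x) x@regionIds)

#' @describeIn nRegions regions of a fit
#' @export
setMethod("nRegions", "LocaNMFFit", function(x) length(x@ranks))

#' @describeIn fitDiagnostics diagnostics list of a fit
#' @export
setMethod("fitDiagnostics", "LocaNMFFit", function(x) x@diagnostics)

setMethod("show", "SemiNMFFit", function(object) {
  cat(class(object), ":", ncol(object@A), "components,",
      nrow(object@A), "pixels x", ncol(object@C), "frames\n")
})

setMethod("show", "LocaNMFFit", function(object) {
  cat("LocaNMFFit:", ncol(object@A), "components over",
      length(object@ranks), "regions (", nrow(object@A), "pixels x",
      ncol(object@C), "frames )\n")
  d <- object@diagnostics
  if (length(d$r2ByRegion))
    cat(sprintf("  min region R2 = %.4f; min localization = %.3f\n",
                min(d$r2ByRegion), min(d$locByComponent)))
  cat("  converged: R2 =", d$converged$r2,
      ", localization =", d$converged$localization, "\n")
})
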