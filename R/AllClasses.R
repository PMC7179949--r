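#' @import methods
NULL

#' Atlas: a 2-D partition of the field of view into brain regions
#'
#' An \code{Atlas} stores an integer label image partitioning the in-FOV
#' pixels into J disjoint regions (label 0 marks pixels outside the field of
#' view, which are excluded from all matrices), together with the fixed
#' flattening used by every pixel-indexed matrix in the package: in-FOV
#' pixels are enumerated row-major (scan rows top to bottom, left to right),
#' pixel centers sit at integer (row, col) coordinates and distances are in
#' pixel units.
#'
#' @slot labels integer matrix (H x W); value j > 0 assigns the pixel to the
#'   j-th original region label, 0 = outside the field of view.
#' @slot regionIds integer vector of the J original (positive) region labels,
#'   in increasing order; internal region index j refers to
#'   \code{regionIds[j]}.
#' @slot regionNames character vector of length J of region acronyms
#'   (\code{NA} where no name was supplied).
#' @slot pixelCoords integer matrix (N x 2) of (row, col) coordinates of the
#'   in-FOV pixels in flattening order.
#' @slot pixelRegion integer vector of length N; internal region index
#'   (1..J) of each in-FOV pixel.
#'
#' @seealso \code{\link{loadAtlas}}, \code{\link{distanceFields}},
#'   \code{\link{makeSyntheticAtlas}}
#' @export
setClass("Atlas",
  representation(
    labels = "matrix",
    regionIds = "integer",
    regionNames = "character",
    pixelCoords = "matrix",
    pixelRegion = "integer"
  )
)

setValidity("Atlas", function(object) {
  msg <- NULL
  J <- length(object@regionIds)
  N <- nrow(object@pixelCoords)
  if (J < 1) msg <- c(msg, "atlas must contain at least one region")
  if (any(object@regionIds <= 0)) msg <- c(msg, "region ids must be positive")
  if (anyDuplicated(object@regionIds)) msg <- c(msg, "region ids must be unique")
  if (length(object@regionNames) != J)
    msg <- c(msg, "regionNames must have one entry per region")
  if (length(object@pixelRegion) != N)
    msg <- c(msg, "pixelRegion must have one entry per in-FOV pixel")
  if (N > 0 && (min(object@pixelRegion) < 1 || max(object@pixelRegion) > J))
    msg <- c(msg, "pixelRegion values must index regionIds")
  if (N > 0 && !all(tabulate(object@pixelRegion, nbins = J) >= 1L))
    msg <- c(msg, "every region must own at least one pixel")
  if (is.null(msg)) TRUE else msg
})

#' Low-rank factored video
#'
#' A video Y (pixels x time) held as the product of a spatial factor U
#' (N x Kd) and a temporal factor V (Kd x T), optionally with a cached LQ
#' split V = L Q (L lower-triangular Kd x Kd, Q with orthonormal rows).
#' All heavy computation in the package operates on (U, L) only, never on a
#' dense N x T array.
#'
#' @slot U numeric matrix (N x Kd), spatial factors.
#' @slot V numeric matrix (Kd x T), temporal factors.
#' @slot L numeric matrix; lower-triangular Kd x Kd LQ cache (0 x 0 when
#'   absent).
#' @slot Q numeric matrix; orthonormal-row Kd x T LQ cache (0 x 0 when
#'   absent).
#' @slot frameRate numeric scalar, frames per second (NA when unknown).
#'
#' @seealso \code{\link{lowRankVideo}}, \code{\link{truncatedSVD}},
#'   \code{\link{lqDecompose}}
#' @export
setClass("LowRankVideo",
  representation(
    U = "matrix",
    V = "matrix",
    L = "matrix",
    Q = "matrix",
    frameRate = "numeric"
  )
)

setValidity("LowRankVideo", function(object) {
  msg <- NULL
  Kd <- ncol(object@U)
  if (nrow(object@V) != Kd)
    msg <- c(msg, "nrow(V) must equal ncol(U)")
  # stacked representations (hemodynamic residual, dF/F) may carry more
  # columns than the matrix rank, so only the LQ-feasibility bound applies
  if (Kd > ncol(object@V))
    msg <- c(msg, "rank Kd must not exceed T")
  if (nrow(object@L) > 0) {
    if (!all(dim(object@L) == c(Kd, Kd)) || !all(dim(object@Q) == dim(object@V)))
      msg <- c(msg, "LQ cache dimensions inconsistent with V")
    else {
      nv <- sqrt(sum(object@V^2))
      rel <- sqrt(sum((object@L %*% object@Q - object@V)^2))
      if (nv > 0 && rel / nv > 1e-8)
        msg <- c(msg, "LQ cache does not reconstruct V")
      if (sqrt(sum((tcrossprod(object@Q) - diag(Kd))^2)) > 1e-6)
        msg <- c(msg, "Q rows are not orthonormal")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Semi-NMF decomposition of a low-rank video
#'
#' Holds spatial components A (N x K, nonnegative), subspace temporal mixing
#' B (K x Kd) and materialized temporal components C = B Q (K x T).
#'
#' @slot A numeric matrix (N x K), nonnegative spatial components, each
#'   column max-normalized to 1.
#' @slot B numeric matrix (K x Kd), temporal mixing weights in the LQ
#'   subspace.
#' @slot C numeric matrix (K x T), temporal components.
#'
#' @seealso \code{\link{vanillaNMF}}, \code{\link{locaNMF}}
#' @export
setClass("SemiNMFFit",
  representation(A = "matrix", B = "matrix", C = "matrix")
)

setValidity("SemiNMFFit", function(object) {
  msg <- NULL
  K <- ncol(object@A)
  if (nrow(object@B) != K) msg <- c(msg, "nrow(B) must equal ncol(A)")
  if (nrow(object@C) != K) msg <- c(msg, "nrow(C) must equal ncol(A)")
  if (length(object@A) && min(object@A) < 0)
    msg <- c(msg, "spatial components must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Atlas-localized semi-NMF fit
#'
#' A \code{SemiNMFFit} whose components are each anchored to an atlas region,
#' together with the per-component penalty multipliers, per-region component
#' counts and fit diagnostics produced by the adaptive search.
#'
#' @slot phi integer vector of length K; internal atlas region index of each
#'   component.
#' @slot lambdas numeric vector of length K; final localization penalty
#'   multipliers.
#' @slot ranks integer vector of length J; number of components per region.
#' @slot regionIds integer vector of length J; original atlas labels, aligned
#'   with \code{ranks}.
#' @slot diagnostics list with elements \code{r2ByRegion} (length J),
#'   \code{locByComponent} (length K), \code{objectiveTrace} (per-sweep
#'   values of the squared-error objective), \code{itersUsed} (counts for the
#'   rank, lambda and HALS loops) and \code{converged} (logical flags).
#'
#' @seealso \code{\link{locaNMF}}
#' @export
setClass("LocaNMFFit",
  contains = "SemiNMFFit",
  representation(
    phi = "integer",
    lambdas = "numeric",
    ranks = "integer",
    regionIds = "integer",
    diagnostics = "list"
  )
)

setValidity("LocaNMFFit", function(object) {
  msg <- NULL
  K <- ncol(object@A)
  J <- length(object@ranks)
  if (length(object@phi) != K) msg <- c(msg, "phi must map every component")
  if (length(object@lambdas) != K) msg <- c(msg, "one lambda per component")
  if (length(object@regionIds) != J) msg <- c(msg, "regionIds/ranks mismatch")
  if (K > 0 && !identical(tabulate(object@phi, nbins = J), as.integer(object@ranks)))
    msg <- c(msg, "ranks must equal the per-region component counts of phi")
  if (length(object@lambdas) && min(object@lambdas) < 0)
    msg <- c(msg, "lambdas must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Region-pair canonical correlation map
#'
#' Symmetric J x J matrix of first canonical correlations between the
#' temporal component sets of every pair of atlas regions; the diagonal is 1.
#'
#' @slot values numeric symmetric matrix (J x J), entries in [0, 1].
#' @slot regionIds integer vector of length J.
#'
#' @seealso \code{\link{ccaMap}}, \code{\link{mapDistance}}
#' @export
setClass("CCAMap",
  representation(values = "matrix", regionIds = "integer")
)

setValidity("CCAMap", function(object) {
  msg <- NULL
  J <- length(object@regionIds)
  if (!all(dim(object@values) == c(J, J)))
    msg <- c(msg, "values must be J x J")
  if (max(abs(object@values - t(object@values))) > 1e-8)
    msg <- c(msg, "values must be symmetric")
  if (any(object@values < -1e-8) || any(object@values > 1 + 1e-8))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (max(abs(diag(object@values) - 1)) > 1e-8)
    msg <- c(msg, "diagonal must be 1")
  if (is.null(msg)) TRUE else msg
})
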