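#' Construct a low-rank video
#'
#' @param U numeric matrix (N x Kd), spatial factors.
#' @param V numeric matrix (Kd x T), temporal factors.
#' @param frameRate frames per second (metadata; NA when unknown).
#' @param lq if TRUE, compute and cache the LQ split of V immediately.
#' @return a \code{\linkS4class{LowRankVideo}}
#' @export
lowRankVideo <- function(U, V, frameRate = NA_real_, lq = FALSE) {
  stopifnotMatrix(U, "U"); stopifnotMatrix(V, "V")
  if (ncol(U) != nrow(V))
    stop("shape mismatch: ncol(U) = ", ncol(U), " but nrow(V) = ", nrow(V))
  obj <- new("LowRankVideo", U = U, V = V,
             L = matrix(0, 0, 0), Q = matrix(0, 0, 0),
             frameRate = as.numeric(frameRate))
  if (lq) obj <- ensureLQ(obj)
  obj
}

#' Truncated-SVD compression of a dense video
#'
#' Compresses a dense pixels-by-time array to the best rank-\code{rank}
#' Frobenius approximation Y ~ U V, with U the left singular vectors scaled
#' by the singular values and V the right singular vectors.
#'
#' @param video dense numeric matrix (N x T).
#' @param rank positive integer, number of components to keep.
#' @param frameRate frames per second (metadata).
#' @return a \code{\linkS4class{LowRankVideo}} of rank \code{rank}
#' @export
truncatedSVD <- function(video, rank, frameRate = NA_real_) {
  stopifnotMatrix(video, "video")
  rank <- as.integer(rank)
  if (length(rank) != 1L || is.na(rank) || rank < 1L)
    stop("rank must be a positive integer")
  if (rank > min(dim(video)))
    stop("rank (", rank, ") exceeds min(dim(video)) = ", min(dim(video)))
  sv <- svd(video, nu = rank, nv = rank)
  U <- sv$u %*% diag(sv$d[seq_len(rank)], rank, rank)
  V <- t(sv$v)
  lowRankVideo(U, V, frameRate = frameRate)
}

#' LQ decomposition of a temporal factor
#'
#' Factors V = L Q with L lower-triangular (Kd x Kd) and Q (Kd x T) having
#' orthonormal rows, via QR of t(V). Row signs are flipped jointly in L and
#' Q so that diag(L) >= 0, making the split deterministic.
#'
#' @param V numeric matrix (Kd x T), Kd <= T.
#' @return list with elements \code{L} and \code{Q}
#' @export
lqDecompose <- function(V) {
  stopifnotMatrix(V, "V")
  Kd <- nrow(V)
  if (Kd > ncol(V))
    stop("LQ needs Kd <= T: no orthonormal row basis of size ", Kd,
         " exists in dimension ", ncol(V))
  qrv <- qr(t(V))
  if (identical(qrv$pivot, seq_len(Kd))) {
    # Householder QR of t(V) without pivoting: directly gives V = L Q
    L <- t(qr.R(qrv))
    Q <- t(qr.Q(qrv))
  } else {
    # rank-deficient input made qr() pivot; build the split by modified
    # Gram-Schmidt over rows of V, completing Q with orthonormal rows for
    # zero pivots (so Q Q' = I and the matching rows of L are zero)
    L <- matrix(0, Kd, Kd)
    Q <- matrix(0, Kd, ncol(V))
    tol <- max(dim(V)) * .Machine$double.eps * max(abs(V), 1)
    for (i in seq_len(Kd)) {
      r <- V[i, ]
      for (pass in 1:2) {   # twice-is-enough re-orthogonalization
        for (j in seq_len(i - 1L)) {
          pj <- sum(r * Q[j, ])
          if (pass == 1L) L[i, j] <- L[i, j] + pj
          r <- r - pj * Q[j, ]
        }
      }
      nr <- sqrt(sum(r^2))
      if (nr > tol) {
        L[i, i] <- nr
        Q[i, ] <- r / nr
      } else {
        # orthonormal filler row from the canonical basis
        for (e in seq_len(ncol(V))) {
          r <- numeric(ncol(V)); r[e] <- 1
          for (j in seq_len(i - 1L)) r <- r - sum(r * Q[j, ]) * Q[j, ]
          nr <- sqrt(sum(r^2))
          if (nr > 0.5) { Q[i, ] <- r / nr; break }
        }
      }
    }
  }
  s <- sign(diag(L))
  s[s == 0] <- 1
  L <- sweep(L, 2L, s, "*")
  Q <- Q * s
  list(L = L, Q = Q)
}

#' Ensure the LQ cache of a low-rank video is present
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}}
#' @return the video with slots L and Q populated
#' @export
ensureLQ <- function(lrv) {
  stopifnot(is(lrv, "LowRankVideo"))
  if (nrow(lrv@L) > 0) return(lrv)
  lq <- lqDecompose(lrv@V)
  lrv@L <- lq$L
  lrv@Q <- lq$Q
  validObject(lrv)
  lrv
}

#' Per-pixel variance terms in the temporal subspace
#'
#' For each in-FOV pixel n, returns the subspace representation U(n) L of its
#' reconstructed trace and the sum over time of squared deviations of that
#' trace from its temporal mean, computed without materializing any N x T
#' array: with qbar = Q 1/T, the deviation term is
#' ||U(n) L||^2 - T (U(n) L qbar)^2, which equals the dense time-domain sum
#' exactly. Pixels whose deviation term falls below \code{tol} (dead or
#' constant pixels) are flagged for exclusion from region R-squared averages.
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}} (LQ cache computed on
#'   demand if absent).
#' @param tol exclusion threshold on the denominator.
#' @return list with \code{UL} (N x Kd), \code{denom} (length N) and
#'   \code{keep} (logical, length N)
#' @export
pixelVarianceTerms <- function(lrv, tol = 1e-12) {
  lrv <- ensureLQ(lrv)
  UL <- lrv@U %*% lrv@L
  Tn <- ncol(lrv@V)
  qbar <- rowMeans(lrv@Q)
  m <- drop(UL %*% qbar)        # temporal mean of each pixel trace
  denom <- rowSums(UL^2) - Tn * m^2
  denom[denom < 0] <- 0          # guard tiny negative round-off
  list(UL = UL, denom = denom, keep = denom > tol)
}

#' @describeIn nPixels number of pixels of a low-rank video
#' @export
setMethod("nPixels", "LowRankVideo", function(x) nrow(x@U))

#' @describeIn nTimepoints number of frames of a low-rank video
#' @export
setMethod("nTimepoints", "LowRankVideo", function(x) ncol(x@V))

#' Rank of the factored representation
#' @param lrv a \code{\linkS4class{LowRankVideo}}
#' @return integer Kd
#' @export
videoRank <- function(lrv) ncol(lrv@U)

#' @describeIn reconstruct dense N x T product U V
#' @export
setMethod("reconstruct", "LowRankVideo", function(x) x@U %*% x@V)

setMethod("show", "LowRankVideo", function(object) {
  cat("LowRankVideo:", nPixels(object), "pixels x", nTimepoints(object),
      "frames, rank", videoRank(object),
      if (nrow(object@L) > 0) "(LQ cached)" else "", "\n")
  if (!is.na(object@frameRate))
    cat("  frame rate:", object@frameRate, "Hz\n")
})
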