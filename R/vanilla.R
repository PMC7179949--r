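#' Vanilla semi-NMF baseline with random initialization
#'
#' The unlocalized baseline: spatial components are initialized as
#' independent Bernoulli(p) pixel masks, each temporal component as the mean
#' trace of its masked pixels, then alternating [normalize, spatial HALS,
#' temporal HALS] sweeps with no distance penalty. All computation stays in
#' the LQ subspace. Different seeds generally give different solutions (the
#' initialization-dependence of unconstrained semi-NMF).
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}}.
#' @param K number of components (>= 1).
#' @param maxitersHals number of HALS sweeps; default 30.
#' @param seed RNG seed for the Bernoulli masks.
#' @param p Bernoulli probability of including a pixel in a mask;
#'   default 0.1.
#' @return a \code{\linkS4class{SemiNMFFit}}
#' @export
vanillaNMF <- function(lrv, K, maxitersHals = 30L, seed = 1L, p = 0.1) {
  stopifnot(is(lrv, "LowRankVideo"))
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  lrv <- ensureLQ(lrv)
  U <- lrv@U; L <- lrv@L
  N <- nrow(U)

  init <- withSeed(seed, {
    A <- matrix(0, N, K)
    for (k in seq_len(K)) {
      mask <- stats::rbinom(N, 1L, p)
      tries <- 0L
      while (sum(mask) == 0L && tries < 100L) {
        mask <- stats::rbinom(N, 1L, p)
        tries <- tries + 1L
      }
      if (sum(mask) == 0L)
        stop("could not draw a nonempty Bernoulli mask for component ", k)
      A[, k] <- mask
    }
    A
  })
  A <- init
  # C_k = mean over masked pixels of their traces; in subspace:
  # B_k = mean(U[mask,]) L
  B <- matrix(0, K, ncol(L))
  for (k in seq_len(K)) {
    mask <- A[, k] > 0
    B[k, ] <- colMeans(U[mask, , drop = FALSE]) %*% L
  }

  for (it in seq_len(maxitersHals)) {
    # normalize temporal rows to unit norm, absorbing scale into A
    nb <- sqrt(rowSums(B^2))
    nz <- nb > 0
    B[nz, ] <- B[nz, , drop = FALSE] / nb[nz]
    A[, nz] <- sweep(A[, nz, drop = FALSE], 2L, nb[nz], "*")
    A <- halsSpatial(U, L, A, B)
    B <- halsTemporal(U, L, A, B)
  }
  new(Class = "SemiNMFFit", A = A, B = B, C = B %*% lrv@Q)
}
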