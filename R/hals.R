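# Hierarchical alternating least squares (HALS) updates for the localized
# semi-NMF objective, operating entirely in the Kd-dimensional temporal
# subspace: the data enter only through U (N x Kd) and L (Kd x Kd), using
# the identity ||U V - A C||_F = ||U L - A B||_F for C = B Q.

#' One penalized spatial HALS sweep
#'
#' Updates the spatial components sequentially:
#' a_k <- [ a_k + ( (U L B')_k - (A B B')_k - lambda_k d_k ) / ||b_k||^2 ]_+ ,
#' each update using the already-updated columns of A (block coordinate
#' descent). Components with ||b_k||^2 below \code{tol} are skipped.
#' With lambda = 0 this is the unpenalized semi-NMF spatial sweep; with
#' lambda_k > 0 the term lambda_k d_k shrinks mass far from the component's
#' atlas region.
#'
#' @param U,L low-rank video factors (N x Kd and Kd x Kd).
#' @param A current spatial components (N x K), nonnegative.
#' @param B current temporal mixing (K x Kd).
#' @param lambdas penalty multipliers (length K); NULL means all zero.
#' @param D per-component distance columns (N x K), d_k = distance field of
#'   the component's region; NULL means all zero (no localization).
#' @param tol skip threshold on ||b_k||^2.
#' @return updated A
#' @export
halsSpatial <- function(U, L, A, B, lambdas = NULL, D = NULL, tol = 1e-12) {
  K <- ncol(A)
  if (is.null(lambdas)) lambdas <- numeric(K)
  P <- U %*% tcrossprod(L, B)   # N x K : (U L B')
  G <- tcrossprod(B)            # K x K : B B'
  for (k in seq_len(K)) {
    nb <- G[k, k]
    if (nb < tol) next
    pen <- if (is.null(D)) 0 else lambdas[k] * D[, k]
    ak <- A[, k] + (P[, k] - drop(A %*% G[, k]) - pen) / nb
    A[, k] <- pmax(ak, 0)
  }
  A
}

#' One temporal HALS sweep
#'
#' Updates the mixing rows sequentially:
#' b_k <- b_k + ( (A' U)_k L - (A' A)_k B ) / ||a_k||^2 ,
#' block coordinate descent on ||U L - A B||_F^2 over rows of B. Components
#' with ||a_k||^2 below \code{tol} are skipped.
#'
#' @inheritParams halsSpatial
#' @param tol skip threshold on ||a_k||^2.
#' @return updated B
#' @export
halsTemporal <- function(U, L, A, B, tol = 1e-12) {
  K <- ncol(A)
  AtUL <- crossprod(A, U) %*% L  # K x Kd
  H <- crossprod(A)              # K x K
  for (k in seq_len(K)) {
    na <- H[k, k]
    if (na < tol) next
    B[k, ] <- B[k, ] + (AtUL[k, ] - drop(H[k, ] %*% B)) / na
  }
  B
}

#' Max-normalize spatial components
#'
#' Rescales every nonzero column of A to satisfy the sup-norm constraint
#' max_n a_k(n) = 1, multiplying the same factor into the corresponding row
#' of B so the product A B is unchanged. Identically-zero columns are left
#' untouched and reported for pruning.
#'
#' @param A spatial components (N x K), nonnegative.
#' @param B temporal mixing (K x Kd).
#' @return list with rescaled \code{A}, \code{B} and logical \code{zero}
#'   flagging all-zero components
#' @export
normalizeComponents <- function(A, B) {
  mx <- apply(A, 2L, max)
  zero <- mx <= 0
  sc <- ifelse(zero, 1, mx)
  A <- sweep(A, 2L, sc, "/")
  B <- B * sc
  list(A = A, B = B, zero = zero)
}

# squared-error objective in the subspace
halsObjective <- function(U, L, A, B) {
  sum((U %*% L - A %*% B)^2)
}
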