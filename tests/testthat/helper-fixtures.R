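# Shared fixtures: everything is generated in code at test time.

# random low-rank video with optional LQ cache
randomLRV <- function(N, Kd, Tn, seed = 1, lq = TRUE) {
  set.seed(seed)
  U <- matrix(rnorm(N * Kd), N, Kd)
  V <- matrix(rnorm(Kd * Tn), Kd, Tn)
  lowRankVideo(U, V, frameRate = 30, lq = lq)
}

# two-block vertical split atlas on an H x W grid
twoBlockAtlas <- function(H = 6, W = 6) {
  lab <- matrix(rep(c(1L, 2L), each = H * W / 2), H, W)
  loadAtlas(lab)
}

# dense spatial HALS sweep straight from the update formula, using
# C = B Q and Y = U V (the quantities the subspace code never materializes)
denseSpatialSweep <- function(Y, C, A, lambdas, D) {
  K <- ncol(A)
  for (k in seq_len(K)) {
    ck2 <- sum(C[k, ]^2)
    if (ck2 < 1e-12) next
    g <- drop(Y %*% C[k, ]) - drop(A %*% (C %*% C[k, ])) - lambdas[k] * D[, k]
    A[, k] <- pmax(A[, k] + g / ck2, 0)
  }
  A
}

# dense temporal HALS sweep from the update formula
denseTemporalSweep <- function(Y, A, C) {
  K <- ncol(A)
  for (k in seq_len(K)) {
    ak2 <- sum(A[, k]^2)
    if (ak2 < 1e-12) next
    C[k, ] <- C[k, ] + (drop(crossprod(A[, k], Y)) -
                          drop(crossprod(A)[k, ] %*% C)) / ak2
  }
  C
}

relErr <- function(x, y) {
  d <- sqrt(sum((x - y)^2))
  n <- sqrt(sum(y^2))
  if (n == 0) d else d / n
}
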