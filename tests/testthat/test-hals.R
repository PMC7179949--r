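test_that("one unpenalized spatial update solves the rank-1 least squares", {
  set.seed(20)
  aTrue <- abs(rnorm(30)); aTrue <- aTrue / max(aTrue)
  lrv <- lowRankVideo(aTrue %o% rnorm(5), matrix(rnorm(5 * 60), 5, 60),
                      lq = TRUE)
  B <- matrix(rnorm(5), 1, 5)
  A0 <- matrix(abs(rnorm(30)), 30, 1)
  A1 <- halsSpatial(lrv@U, lrv@L, A0, B)
  # closed form: clipped least-squares profile for fixed b
  UL <- lrv@U %*% lrv@L
  closed <- pmax(drop(UL %*% t(B)) / sum(B^2), 0)
  expect_equal(A1[, 1], closed, tolerance = 1e-10)
})

test_that("a saturating penalty zeroes every out-of-region pixel in one sweep", {
  set.seed(21)
  atl <- twoBlockAtlas(4, 4)
  D <- distanceFields(atl)
  lrv <- randomLRV(16, 3, 40, seed = 21)
  A <- matrix(abs(rnorm(16 * 2)), 16, 2)
  B <- matrix(rnorm(2 * 3), 2, 3)
  lamSat <- max(abs(lrv@U %*% tcrossprod(lrv@L, B))) * 100 /
    min(D[D > 0])
  A1 <- halsSpatial(lrv@U, lrv@L, A, B, lambdas = c(lamSat, lamSat),
                    D = D[, c(1, 2)])
  expect_true(all(A1[D[, 1] > 0, 1] == 0))
  expect_true(all(A1[D[, 2] > 0, 2] == 0))
})

test_that("subspace spatial sweep matches the dense update formula", {
  lrv <- randomLRV(40, 5, 120, seed = 22)
  set.seed(23)
  A <- matrix(abs(rnorm(40 * 3)), 40, 3)
  B <- matrix(rnorm(3 * 5), 3, 5)
  atl <- loadAtlas(matrix(rep(1:2, each = 20), 5, 8))
  D <- distanceFields(atl)[, c(1, 2, 1)]
  lambdas <- c(0.3, 0, 1.1)
  Asub <- halsSpatial(lrv@U, lrv@L, A, B, lambdas, D)
  Adense <- denseSpatialSweep(reconstruct(lrv), B %*% lrv@Q, A, lambdas, D)
  expect_lt(relErr(Asub, Adense), 1e-8)
})

test_that("normalization preserves the product and flags dead components", {
  set.seed(24)
  A <- matrix(abs(rnorm(20 * 3)), 20, 3)
  A[, 2] <- A[, 2] * 2 / max(A[, 2])   # max 2
  A[, 3] <- 0
  B <- matrix(rnorm(3 * 4), 3, 4)
  nc <- normalizeComponents(A, B)
  expect_equal(apply(nc$A[, 1:2], 2, max), c(1, 1), tolerance = 1e-12)
  expect_lt(sqrt(sum((nc$A %*% nc$B - A %*% B)^2)), 1e-10)
  expect_equal(nc$zero, c(FALSE, FALSE, TRUE))
})

test_that("temporal sweeps reach closed forms and match the dense update", {
  lrv <- randomLRV(30, 4, 90, seed = 25)
  UL <- lrv@U %*% lrv@L

  # single component: exact closed form after one update
  set.seed(26)
  a1 <- matrix(abs(rnorm(30)), 30, 1)
  B1 <- halsTemporal(lrv@U, lrv@L, a1, matrix(0, 1, 4))
  expect_equal(B1[1, ], drop(crossprod(a1, UL)) / sum(a1^2),
               tolerance = 1e-10)

  # orthogonal spatial columns: one sweep gives the joint least squares
  Aorth <- matrix(0, 30, 3)
  Aorth[1:10, 1] <- 1; Aorth[11:20, 2] <- 1; Aorth[21:30, 3] <- 1
  B3 <- halsTemporal(lrv@U, lrv@L, Aorth, matrix(0, 3, 4))
  expect_equal(B3, solve(crossprod(Aorth)) %*% crossprod(Aorth, UL),
               tolerance = 1e-10)

  # dense-oracle + objective decrease on a random instance
  A <- matrix(abs(rnorm(30 * 3)), 30, 3)
  B0 <- matrix(rnorm(3 * 4), 3, 4)
  before <- sum((UL - A %*% B0)^2)
  Bsub <- halsTemporal(lrv@U, lrv@L, A, B0)
  Cdense <- denseTemporalSweep(reconstruct(lrv), A, B0 %*% lrv@Q)
  expect_lt(relErr(Bsub %*% lrv@Q, Cdense), 1e-8)
  expect_lte(sum((UL - A %*% Bsub)^2), before + 1e-10)
})

test_that("unpenalized HALS objective is non-increasing sweep after sweep", {
  for (seed in 1:20) {
    lrv <- randomLRV(25, 4, 50, seed = seed)
    set.seed(seed + 500)
    A <- matrix(abs(rnorm(25 * 3)), 25, 3)
    B <- matrix(rnorm(3 * 4), 3, 4)
    obj <- sum((lrv@U %*% lrv@L - A %*% B)^2)
    for (it in 1:5) {
      A <- halsSpatial(lrv@U, lrv@L, A, B)
      nc <- normalizeComponents(A, B)
      A <- nc$A; B <- nc$B
      B <- halsTemporal(lrv@U, lrv@L, A, B)
      newObj <- sum((lrv@U %*% lrv@L - A %*% B)^2)
      expect_lte(newObj, obj + 1e-10)
      obj <- newObj
    }
  }
})
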