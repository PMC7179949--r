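test_that("region R-squared matches its dense time-domain definition", {
  atl <- twoBlockAtlas(4, 6)
  lrv <- randomLRV(24, 3, 80, seed = 30)
  set.seed(31)
  A <- matrix(abs(rnorm(24 * 2)), 24, 2)
  B <- matrix(rnorm(2 * 3), 2, 3)

  # perfect fit: R2 = 1 everywhere (A B = U L by construction)
  lq <- lqDecompose(lrv@V)
  Aperf <- cbind(pmax(lrv@U, 0), pmax(-lrv@U, 0))
  Bperf <- rbind(lq$L, -lq$L)
  expect_equal(regionR2(lrv, Aperf, Bperf, atl), c(1, 1), tolerance = 1e-10)

  # dense oracle
  r2 <- regionR2(lrv, A, B, atl)
  Y <- reconstruct(lrv)
  Yhat <- A %*% (B %*% lrv@Q)
  ratio <- rowSums((Y - Yhat)^2) / rowSums((Y - rowMeans(Y))^2)
  for (j in 1:2)
    expect_equal(r2[j], 1 - mean(ratio[atl@pixelRegion == j]),
                 tolerance = 1e-8)

  # null model on mean-zero traces: R2 = 0
  Vc <- lrv@V - rowMeans(lrv@V)
  lrvc <- lowRankVideo(lrv@U, Vc, lq = TRUE)
  r0 <- regionR2(lrvc, matrix(0, 24, 1), matrix(0, 1, 3), atl)
  expect_equal(r0, c(0, 0), tolerance = 1e-8)
})

test_that("localization score measures in-region squared mass", {
  atl <- twoBlockAtlas(4, 6)   # regions of 12 pixels each
  A <- matrix(0, 24, 3)
  A[atl@pixelRegion == 1, 1] <- runif(12)        # fully inside
  A[1:3, 2] <- 0.5; A[which(atl@pixelRegion == 2)[1:3], 2] <- 0.5  # half/half
  loc <- localizationScore(A, c(1L, 1L, 2L), atl)
  expect_equal(loc[1], 1)
  expect_equal(loc[2], 0.5)
  expect_equal(loc[3], 1)  # zero column: vacuously localized, flagged
  expect_equal(attr(loc, "zero"), c(FALSE, FALSE, TRUE))
})

test_that("initialization recovers planted per-region signals", {
  set.seed(32)
  atl <- twoBlockAtlas(6, 8)  # 2 regions x 24 pixels
  # exact rank-1 nonnegative signal per region
  a1 <- abs(rnorm(24)) + 0.1; a2 <- abs(rnorm(24)) + 0.1
  A0 <- matrix(0, 48, 2)
  A0[atl@pixelRegion == 1, 1] <- a1
  A0[atl@pixelRegion == 2, 2] <- a2
  C0 <- matrix(rnorm(2 * 200), 2, 200)
  lrv <- lowRankVideo(A0, C0, lq = TRUE)
  init <- initSNMF(lrv@U, lrv@L, atl, ranks = c(1L, 1L), maxitersHals = 20)
  expect_equal(init$phi, c(1L, 2L))
  expect_equal(dim(init$A), c(48L, 2L))
  # support confined to each region at init, profile recovered
  expect_true(all(init$A[atl@pixelRegion == 2, 1] == 0))
  cs <- cosineSimilarity(init$A, A0)
  expect_gte(cs[1, 1], 0.999)
  expect_gte(cs[2, 2], 0.999)

  expect_error(initSNMF(lrv@U, lrv@L, atl, ranks = c(0L, 1L)), ">= 1")
  expect_warning(initSNMF(lrv@U, lrv@L, atl, ranks = c(1L, 30L)), "clamping")
})

test_that("null (all-zero) video takes the guard path", {
  atl <- twoBlockAtlas(4, 4)
  lrv <- lowRankVideo(matrix(0, 16, 2), matrix(0, 2, 50), lq = TRUE)
  fit <- suppressWarnings(locaNMF(lrv, atl, locaNMFConfig(maxitersHals = 5L)))
  d <- fitDiagnostics(fit)
  expect_equal(d$itersUsed$K, 1L)
  expect_equal(d$r2ByRegion, c(1, 1))
  expect_equal(ncol(spatialComponents(fit)), 2L)  # J * kMin survive
  expect_equal(mixingWeights(fit), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("two disjoint rank-1 regions are recovered to high cosine", {
  set.seed(33)
  atl <- twoBlockAtlas(8, 8)
  A0 <- matrix(0, 64, 2)
  A0[atl@pixelRegion == 1, 1] <- abs(rnorm(32)) + 0.2
  A0[atl@pixelRegion == 2, 2] <- abs(rnorm(32)) + 0.2
  C0 <- matrix(rnorm(2 * 300), 2, 300)
  lrv <- lowRankVideo(A0, C0, lq = TRUE)
  fit <- locaNMF(lrv, atl, locaNMFConfig(r2Thr = 0.99, locThr = 0.7))
  m <- matchComponents(A0, spatialComponents(fit))
  expect_gte(min(m$similarity), 0.99)
})

test_that("the fit is identical through subspace and dense arithmetic", {
  # same video handed over as (U, V) factors and as a dense factorization
  # (U = Y, V = I): every LQ identity must make the two runs coincide
  set.seed(34)
  atl <- twoBlockAtlas(8, 8)
  A0 <- matrix(0, 64, 2)
  A0[atl@pixelRegion == 1, 1] <- runif(32)
  A0[atl@pixelRegion == 2, 2] <- runif(32)
  A0 <- A0 + 0.05
  C0 <- matrix(rnorm(2 * 40), 2, 40)
  Y <- A0 %*% C0
  cfg <- locaNMFConfig(r2Thr = 0.95, locThr = 0.7, maxitersK = 3L)
  fit1 <- locaNMF(lowRankVideo(A0, C0, lq = TRUE), atl, cfg)
  fit2 <- locaNMF(lowRankVideo(Y, diag(40), lq = TRUE), atl, cfg)
  expect_lt(relErr(spatialComponents(fit2), spatialComponents(fit1)), 1e-6)
  expect_lt(relErr(reconstruct(fit2), reconstruct(fit1)), 1e-6)
})

test_that("raising the penalty never decreases localization at fixed B", {
  set.seed(35)
  atl <- twoBlockAtlas(6, 6)
  D <- distanceFields(atl)
  lrv <- randomLRV(36, 3, 60, seed = 35)
  B <- matrix(rnorm(1 * 3), 1, 3)
  lamSeq <- c(0, 10^seq(-4, 2, length.out = 10)) *
    max(abs(lrv@U %*% tcrossprod(lrv@L, B)))
  prev <- -Inf
  for (lam in lamSeq) {
    A <- matrix(abs(rnorm(36)), 36, 1)
    for (it in 1:200)
      A <- halsSpatial(lrv@U, lrv@L, A, B, lambdas = lam,
                       D = D[, 1, drop = FALSE])
    loc <- localizationScore(A, 1L, atl)[1]
    expect_gte(loc, prev - 1e-9)
    prev <- loc
  }
})

test_that("near-total localization confines supports to their regions", {
  set.seed(36)
  atl <- twoBlockAtlas(8, 8)
  A0 <- matrix(0, 64, 2)
  A0[atl@pixelRegion == 1, 1] <- runif(32) + 0.1
  A0[atl@pixelRegion == 2, 2] <- runif(32) + 0.1
  lrv <- lowRankVideo(A0 + 0.02, matrix(rnorm(2 * 200), 2, 200), lq = TRUE)
  fit <- locaNMF(lrv, atl,
                 locaNMFConfig(r2Thr = 0.9, locThr = 1 - 1e-9,
                               maxitersK = 2L, maxitersLambda = 200L))
  A <- spatialComponents(fit)
  for (k in seq_len(ncol(A)))
    expect_true(all(A[atl@pixelRegion != componentRegions(fit)[k], k] == 0))
})

test_that("vanilla semi-NMF recovers rank-1 data but is seed dependent", {
  set.seed(37)
  aTrue <- abs(rnorm(50)) + 0.1
  cTrue <- rnorm(150)
  lrv <- lowRankVideo(matrix(aTrue, 50, 1), matrix(cTrue, 1, 150), lq = TRUE)
  fit <- vanillaNMF(lrv, K = 1, maxitersHals = 50, seed = 1)
  expect_gte(cosineSimilarity(spatialComponents(fit),
                              matrix(aTrue, 50, 1))[1, 1], 0.999)

  # reproducible per seed, generally different across seeds
  atl <- twoBlockAtlas(8, 8)
  sim <- simulateDataset(atl, timepoints = 500, seed = 2)
  f1 <- vanillaNMF(sim$video, K = 2, seed = 5)
  f2 <- vanillaNMF(sim$video, K = 2, seed = 5)
  f3 <- vanillaNMF(sim$video, K = 2, seed = 6)
  expect_equal(spatialComponents(f1), spatialComponents(f2))
  expect_gt(relErr(spatialComponents(f3), spatialComponents(f1)), 1e-6)
})
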