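test_that("low-pass filter passes DC, kills high frequencies, guards Nyquist", {
  fr <- 30
  V <- matrix(5, 2, 200)
  expect_equal(lowpassTemporal(V, 1, fr), V, tolerance = 1e-8)

  # sinusoid far above cutoff: amplitude reduced below 5%
  tt <- seq_len(3000)
  cutoff <- 1; freqHz <- 14 * cutoff
  x <- sin(2 * pi * freqHz * tt / fr)
  y <- lowpassTemporal(matrix(x, 1), cutoff, fr, order = 2)
  mid <- 500:2500  # avoid filter edge effects
  expect_lt(max(abs(y[1, mid])), 0.05 * max(abs(x)))

  expect_error(lowpassTemporal(V, fr, fr), "Nyquist")
  expect_error(lowpassTemporal(V, fr / 2, fr), "Nyquist")
})

test_that("hemodynamic regression recovers exact linear relations", {
  fr <- 60; Tn <- 400; N <- 6
  set.seed(4)
  Uh <- matrix(rnorm(N * 2), N, 2)
  Vh <- matrix(rnorm(2 * Tn), 2, Tn)
  hemo <- lowRankVideo(Uh, Vh, frameRate = fr)
  VhL <- lowpassTemporal(Vh, 15, fr)
  b <- runif(N, 0.5, 3); t0 <- runif(N, -2, 2)
  # gcamp trace = b * hemo_lpf + t exactly, in factored form
  gcamp <- lowRankVideo(cbind(b * Uh, t0), rbind(VhL, rep(1, Tn)),
                        frameRate = fr)
  fit <- fitHemodynamics(twoChannelLowRank(gcamp, hemo))
  expect_equal(fit$b, b, tolerance = 1e-8)
  expect_equal(fit$t, t0, tolerance = 1e-8)
})

test_that("degenerate (constant) reference traces fall back to pixel means", {
  fr <- 60; Tn <- 100; N <- 3
  set.seed(5)
  hemo <- lowRankVideo(matrix(1, N, 1), matrix(2, 1, Tn), frameRate = fr)
  Ug <- matrix(rnorm(N * 2), N, 2)
  Vg <- matrix(rnorm(2 * Tn), 2, Tn)
  gcamp <- lowRankVideo(Ug, Vg, frameRate = fr)
  expect_message(fit <- fitHemodynamics(twoChannelLowRank(gcamp, hemo)),
                 "degenerate")
  expect_equal(fit$b, rep(0, N))
  expect_equal(fit$t, rowMeans(Ug %*% Vg), tolerance = 1e-10)
})

test_that("per-pixel coefficients match dense least squares", {
  fr <- 60; Tn <- 300; N <- 20
  set.seed(6)
  hemo <- randomLRV(N, 3, Tn, seed = 6, lq = FALSE)
  hemo@frameRate <- fr
  gcamp <- randomLRV(N, 4, Tn, seed = 7, lq = FALSE)
  gcamp@frameRate <- fr
  fit <- fitHemodynamics(twoChannelLowRank(gcamp, hemo))
  Yg <- reconstruct(gcamp)
  Xh <- hemo@U %*% fit$VhLpf
  for (i in seq_len(N)) {
    cf <- coef(lm(Yg[i, ] ~ Xh[i, ]))
    expect_equal(fit$b[i], unname(cf[2]), tolerance = 1e-8)
    expect_equal(fit$t[i], unname(cf[1]), tolerance = 1e-8)
  }
})

test_that("low-rank correction assembles the printed residual exactly", {
  fr <- 60; Tn <- 250; N <- 15
  hemo <- randomLRV(N, 3, Tn, seed = 8, lq = FALSE); hemo@frameRate <- fr
  gcamp <- randomLRV(N, 4, Tn, seed = 9, lq = FALSE); gcamp@frameRate <- fr
  dat <- twoChannelLowRank(gcamp, hemo)
  fit <- fitHemodynamics(dat)
  out <- applyCorrection(dat, fit)
  expect_equal(videoRank(out), 4 + 3 + 1)
  dense <- reconstruct(gcamp) - fit$b * (hemo@U %*% fit$VhLpf) + fit$t
  expect_lt(relErr(reconstruct(out), dense), 1e-8)

  # b = 0, t = 0 leaves the activity channel untouched
  id <- list(b = rep(0, N), t = rep(0, N), VhLpf = fit$VhLpf)
  expect_lt(relErr(reconstruct(applyCorrection(dat, id)),
                   reconstruct(gcamp)), 1e-10)

  # pixel-count contract
  bad <- list(b = rep(0, N + 1), t = rep(0, N + 1), VhLpf = fit$VhLpf)
  expect_error(applyCorrection(dat, bad), "pixels")
})

test_that("correction is invariant to positive rescaling of the reference", {
  fr <- 60; Tn <- 300; N <- 12
  hemo <- randomLRV(N, 3, Tn, seed = 10, lq = FALSE); hemo@frameRate <- fr
  gcamp <- randomLRV(N, 3, Tn, seed = 11, lq = FALSE); gcamp@frameRate <- fr
  d1 <- twoChannelLowRank(gcamp, hemo)
  hemo2 <- lowRankVideo(7.5 * hemo@U, hemo@V, frameRate = fr)
  d2 <- twoChannelLowRank(gcamp, hemo2)
  y1 <- reconstruct(applyCorrection(d1, fitHemodynamics(d1)))
  y2 <- reconstruct(applyCorrection(d2, fitHemodynamics(d2)))
  expect_lt(relErr(y2, y1), 1e-8)
})

test_that("dF/F maps traces to mean-adjusted form in factored space", {
  # constant pixel maps to exactly zero
  lrv <- lowRankVideo(matrix(5, 1, 1), matrix(1, 1, 8))
  expect_equal(reconstruct(dff(lrv)), matrix(0, 1, 8))

  # hand computation: [8, 12] -> [-0.2, +0.2]
  lrv2 <- lowRankVideo(matrix(1, 1, 1), matrix(c(8, 12), 1, 2))
  expect_equal(reconstruct(dff(lrv2)), matrix(c(-0.2, 0.2), 1, 2),
               tolerance = 1e-12)

  # dense oracle on a random instance with means bounded away from zero
  set.seed(12)
  U <- matrix(rnorm(30 * 3), 30, 3)
  V <- matrix(rnorm(3 * 120), 3, 120)
  V[1, ] <- V[1, ] + 10  # push pixel means away from 0
  U[, 1] <- abs(U[, 1]) + 1
  lrv3 <- lowRankVideo(U, V)
  Y <- reconstruct(lrv3)
  dense <- (Y - rowMeans(Y)) / rowMeans(Y)
  expect_lt(relErr(reconstruct(dff(lrv3)), dense), 1e-8)

  # near-zero-mean pixels are masked to zero
  U4 <- rbind(c(1, 0), c(0, 1))
  V4 <- rbind(c(1, -1, 1, -1), c(5, 6, 5, 6))
  lrv4 <- lowRankVideo(U4, V4)
  expect_message(out <- dff(lrv4), "masked")
  expect_equal(reconstruct(out)[1, ], rep(0, 4))
  expect_equal(attr(out, "masked"), 1L)
})

test_that("end-to-end low-rank correction equals the dense pipeline", {
  fr <- 60; N <- 50 * 50; Tn <- 500
  set.seed(13)
  hemo <- randomLRV(N, 5, Tn, seed = 13, lq = FALSE); hemo@frameRate <- fr
  gcamp <- randomLRV(N, 6, Tn, seed = 14, lq = FALSE); gcamp@frameRate <- fr
  dat <- twoChannelLowRank(gcamp, hemo)
  fit <- fitHemodynamics(dat, cutoffHz = 15, order = 2)
  lowrank <- reconstruct(applyCorrection(dat, fit))

  # dense pipeline: filter every dense pixel trace, per-pixel regression,
  # residual (the factored path filters the Kd temporal rows instead and
  # must agree by linearity)
  Yg <- reconstruct(gcamp)
  Xh <- lowpassTemporal(reconstruct(hemo), 15, fr, order = 2)
  dense <- Yg
  for (i in seq_len(N)) {
    cf <- stats::lm.fit(cbind(1, Xh[i, ]), Yg[i, ])$coefficients
    dense[i, ] <- Yg[i, ] - cf[2] * Xh[i, ] + cf[1]
  }
  expect_lt(relErr(lowrank, dense), 1e-6)
})
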