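# Ground-truthed synthetic widefield data: a Voronoi region partition, one
# Gaussian spatial field per region, and sinusoid-mixture temporal traces
# with additive Gaussian noise. The generated video is returned in exact
# low-rank form (U = planted A, V = planted C), which is also how the
# reference simulations are constructed.

#' Synthetic Voronoi atlas
#'
#' Partitions an H x W grid into J regions by nearest-seed (Euclidean)
#' assignment around J uniformly drawn distinct pixels; ties go to the
#' lowest seed index. Every region is nonempty (each seed belongs to
#' itself). Deterministic per seed.
#'
#' @param height,width grid dimensions.
#' @param J number of regions (1 <= J <= height * width).
#' @param seed RNG seed.
#' @return an \code{\linkS4class{Atlas}} covering the full grid
#' @export
makeSyntheticAtlas <- function(height, width, J, seed = 0L) {
  if (J < 1 || J > height * width)
    stop("J must be between 1 and height*width")
  centers <- withSeed(seed, sample.int(height * width, J))
  cr <- ((centers - 1L) %% height) + 1L
  cc <- ((centers - 1L) %/% height) + 1L
  lab <- matrix(0L, height, width)
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  best <- matrix(Inf, height, width)
  for (j in seq_len(J)) {
    d2 <- (rows - cr[j])^2 + (cols - cc[j])^2
    hit <- d2 < best
    lab[hit] <- j
    best[hit] <- d2[hit]
  }
  loadAtlas(lab)
}

#' Planted Gaussian spatial fields
#'
#' One component per region: an isotropic Gaussian bump centered at the
#' per-coordinate median of the region's pixel coordinates, with width
#' sigma_j = 0.2 * sqrt(region pixel count) (proportional to the region's
#' linear size), evaluated over the whole image (not truncated at the
#' region boundary) and peak-normalized to 1.
#'
#' @param atlas an \code{\linkS4class{Atlas}}.
#' @return list with \code{A} (N x J planted spatial components),
#'   \code{centers} (J x 2 medians) and \code{sigma} (length J)
#' @export
simulateSpatial <- function(atlas) {
  J <- nRegions(atlas)
  N <- nPixels(atlas)
  coords <- atlas@pixelCoords
  A <- matrix(0, N, J)
  centers <- matrix(0, J, 2)
  sigma <- numeric(J)
  for (j in seq_len(J)) {
    sel <- atlas@pixelRegion == j
    centers[j, ] <- c(stats::median(coords[sel, 1L]),
                      stats::median(coords[sel, 2L]))
    sigma[j] <- 0.2 * sqrt(sum(sel))
    d2 <- (coords[, 1L] - centers[j, 1L])^2 + (coords[, 2L] - centers[j, 2L])^2
    a <- exp(-d2 / (2 * sigma[j]^2))
    A[, j] <- a / max(a)
  }
  list(A = A, centers = centers, sigma = sigma)
}

#' Planted sinusoid-mixture temporal traces
#'
#' Draws a pool of 10 angular frequencies beta' ~ U(0.5, 0.63); each of the
#' K traces is the sum of 3 sinusoids with amplitudes alpha ~ U(-1.5, 1.5)
#' and frequencies drawn (with replacement) from the pool, plus i.i.d.
#' Gaussian noise of standard deviation \code{noiseSd}, sampled at
#' t = 0 .. T-1 in frame units (at 30 Hz these frequencies correspond to
#' 2.4-3 Hz oscillations).
#'
#' @param K number of traces.
#' @param timepoints number of time points; default 10000.
#' @param seed RNG seed.
#' @param noiseSd trace noise standard deviation; default 0.1.
#' @return list with \code{C} (K x T), \code{alpha} (3 x K), \code{beta}
#'   (3 x K) and \code{betaPool} (length 10)
#' @export
simulateTemporal <- function(K, timepoints = 10000L, seed = 0L, noiseSd = 0.1) {
  Tn <- as.integer(timepoints)
  stopifnot(K >= 1, Tn >= 1)
  withSeed(seed, {
    betaPool <- stats::runif(10, 0.5, 0.63)
    alpha <- matrix(stats::runif(3 * K, -1.5, 1.5), 3, K)
    beta <- matrix(sample(betaPool, 3 * K, replace = TRUE), 3, K)
    tt <- seq_len(Tn) - 1
    C <- matrix(0, K, Tn)
    for (k in seq_len(K)) {
      mu <- alpha[1, k] * sin(beta[1, k] * tt) +
            alpha[2, k] * sin(beta[2, k] * tt) +
            alpha[3, k] * sin(beta[3, k] * tt)
      C[k, ] <- mu + stats::rnorm(Tn, 0, noiseSd)
    }
    list(C = C, alpha = alpha, beta = beta, betaPool = betaPool)
  })
}

#' Ground-truthed synthetic widefield dataset
#'
#' Assembles the planted spatial fields and temporal traces into a low-rank
#' video with U = A_real and V = C_real (rank = J, LQ cache built), plus the
#' ground-truth object. Optionally inflates the rank with pixelwise Gaussian
#' sensor noise components (off by default: the reference construction is
#' exactly low-rank).
#'
#' @param atlas an \code{\linkS4class{Atlas}}.
#' @param timepoints number of time points; default 10000.
#' @param seed RNG seed (temporal draws and, if requested, sensor noise).
#' @param noiseSd trace noise sd; default 0.1.
#' @param sensorNoiseSd if positive, adds a rank-\code{sensorRank}
#'   approximation of pixelwise Gaussian sensor noise; default 0 (off).
#' @param sensorRank rank used for the optional sensor-noise term.
#' @param frameRate frames per second metadata; default 30.
#' @return list with \code{video} (a \code{\linkS4class{LowRankVideo}}) and
#'   \code{truth} (list: \code{A}, \code{C}, \code{alpha}, \code{beta},
#'   \code{betaPool}, \code{centers}, \code{sigma}, \code{noiseSd},
#'   \code{seed})
#' @export
simulateDataset <- function(atlas, timepoints = 10000L, seed = 0L, noiseSd = 0.1,
                            sensorNoiseSd = 0, sensorRank = 5L,
                            frameRate = 30) {
  sp <- simulateSpatial(atlas)
  K <- nRegions(atlas)
  tm <- simulateTemporal(K, timepoints = timepoints, seed = seed, noiseSd = noiseSd)
  U <- sp$A
  V <- tm$C
  if (sensorNoiseSd > 0) {
    E <- withSeed(seed + 1L, {
      Eu <- matrix(stats::rnorm(nrow(U) * sensorRank, 0, sensorNoiseSd),
                   nrow(U), sensorRank)
      Ev <- matrix(stats::rnorm(sensorRank * ncol(V), 0, 1 / sqrt(sensorRank)),
                   sensorRank, ncol(V))
      list(Eu = Eu, Ev = Ev)
    })
    U <- cbind(U, E$Eu)
    V <- rbind(V, E$Ev)
  }
  video <- lowRankVideo(U, V, frameRate = frameRate, lq = TRUE)
  truth <- list(A = sp$A, C = tm$C, alpha = tm$alpha, beta = tm$beta,
                betaPool = tm$betaPool, centers = sp$centers,
                sigma = sp$sigma, noiseSd = noiseSd, seed = seed)
  list(video = video, truth = truth)
}
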