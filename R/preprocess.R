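#' Two-channel low-rank recording
#'
#' Pairs a GCaMP (activity) channel with a hemodynamic (reference) channel
#' recorded over the same pixels and frames, both in low-rank form.
#'
#' @slot gcamp \code{\linkS4class{LowRankVideo}} of the activity channel.
#' @slot hemo \code{\linkS4class{LowRankVideo}} of the reference channel.
#' @export
setClass("TwoChannelLowRank",
  representation(gcamp = "LowRankVideo", hemo = "LowRankVideo"))

setValidity("TwoChannelLowRank", function(object) {
  msg <- NULL
  if (nPixels(object@gcamp) != nPixels(object@hemo))
    msg <- c(msg, "channels must share the pixel grid")
  if (nTimepoints(object@gcamp) != nTimepoints(object@hemo))
    msg <- c(msg, "channels must share the frame count")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TwoChannelLowRank-class
#' @param gcamp,hemo the two channels as \code{\linkS4class{LowRankVideo}}s
#' @return a \code{TwoChannelLowRank}
#' @export
twoChannelLowRank <- function(gcamp, hemo) {
  new("TwoChannelLowRank", gcamp = gcamp, hemo = hemo)
}

#' Zero-phase Butterworth low-pass of temporal factors
#'
#' Filters each row of a temporal factor matrix with a Butterworth low-pass
#' applied forward and backward (zero phase, so no lag is introduced between
#' channels before the hemodynamic regression). DC gain is 1, so constant
#' rows pass through unchanged.
#'
#' @param V numeric matrix (Kd x T), one temporal trace per row.
#' @param cutoffHz cutoff frequency in Hz; must be below the Nyquist
#'   frequency \code{frameRate / 2}.
#' @param frameRate sampling rate in Hz.
#' @param order filter order (default 2).
#' @return filtered matrix of the same shape
#' @export
lowpassTemporal <- function(V, cutoffHz, frameRate, order = 2) {
  stopifnotMatrix(V, "V")
  if (cutoffHz >= frameRate / 2)
    stop("cutoff (", cutoffHz, " Hz) must be below the Nyquist frequency ",
         frameRate / 2, " Hz")
  if (cutoffHz <= 0) stop("cutoff must be positive")
  bf <- signal::butter(order, cutoffHz / (frameRate / 2), type = "low")
  out <- V
  for (i in seq_len(nrow(V)))
    out[i, ] <- zeroPhaseFilter(bf$b, bf$a, V[i, ])
  out
}

# Zero-phase (forward-backward) filtering with odd-extension padding and
# steady-state initial conditions at both ends (previous inputs/outputs as
# if the signal had been constant at its first value), so DC gain is
# exactly 1 and start-up transients are suppressed.
zeroPhaseFilter <- function(b, a, x) {
  n <- length(x)
  m <- max(length(a), length(b)) - 1L
  p <- min(n - 1L, 10L * m)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  dc <- sum(b) / sum(a)
  onePass <- function(z) {
    as.numeric(signal::filter(b, a, z, init.x = rep(z[1], m),
                              init.y = rep(z[1] * dc, m)))
  }
  y <- rev(onePass(rev(onePass(ext))))
  y[(p + 1):(p + n)]
}

#' Per-pixel hemodynamic regression coefficients
#'
#' Fits, for every pixel i, the least-squares model
#' gcamp_i(t) = b_i * hemoLpf_i(t) + t_i, where hemoLpf is the low-passed
#' reference channel. All sufficient statistics are accumulated in the
#' Kd-dimensional subspace; no N x T array is formed. Pixels whose filtered
#' reference trace has (numerically) zero variance fall back to b = 0 and
#' t = the pixel's mean activity.
#'
#' @param data a \code{\linkS4class{TwoChannelLowRank}}.
#' @param cutoffHz low-pass cutoff for the reference channel (default 15 Hz).
#' @param order Butterworth order (default 2).
#' @return list with numeric vectors \code{b}, \code{t} (length N), logical
#'   \code{degenerate} marking fallback pixels, and \code{VhLpf} (the
#'   filtered reference temporal factor, reused by
#'   \code{\link{applyCorrection}})
#' @export
fitHemodynamics <- function(data, cutoffHz = 15, order = 2) {
  stopifnot(is(data, "TwoChannelLowRank"))
  Tn <- nTimepoints(data@gcamp)
  if (Tn < 3) stop("need at least 3 frames for the regression")
  fr <- data@hemo@frameRate
  if (is.na(fr)) fr <- data@gcamp@frameRate
  if (is.na(fr)) stop("frame rate metadata required for filtering")
  VhL <- lowpassTemporal(data@hemo@V, cutoffHz, fr, order)
  Ug <- data@gcamp@U; Vg <- data@gcamp@V; Uh <- data@hemo@U

  # subspace sufficient statistics for per-pixel simple regression
  Ghg <- VhL %*% t(Vg)                 # Kd_h x Kd_g
  Ghh <- tcrossprod(VhL)               # Kd_h x Kd_h
  sxy <- rowSums((Uh %*% Ghg) * Ug)    # sum_t x_i y_i
  sxx <- rowSums((Uh %*% Ghh) * Uh)    # sum_t x_i^2
  mx <- drop(Uh %*% rowMeans(VhL))
  my <- drop(Ug %*% rowMeans(Vg))
  varx <- sxx / Tn - mx^2
  covxy <- sxy / Tn - mx * my

  scale2 <- pmax(sxx / Tn, 0)
  degenerate <- varx <= 1e-12 * pmax(scale2, 1e-300)
  b <- ifelse(degenerate, 0, covxy / varx)
  t0 <- ifelse(degenerate, my, my - b * mx)
  if (any(degenerate))
    message(sum(degenerate), " pixel(s) had a degenerate reference trace; ",
            "falling back to b = 0, t = pixel mean")
  list(b = b, t = t0, degenerate = degenerate, VhLpf = VhL,
       cutoffHz = cutoffHz, order = order)
}

#' Assemble the hemodynamic-corrected video in low-rank form
#'
#' Builds the regression residual directly as a factored video by stacking
#' U = [Ug, -diag(b) Uh, t] and V = [Vg; VhLpf; 1], so the reconstruction
#' equals Yg - diag(b) YhLpf + t at every pixel and the rank grows to
#' Kd(g) + Kd(h) + 1. The appended intercept constant is removed again by
#' the mean adjustment of \code{\link{dff}}.
#'
#' @param data a \code{\linkS4class{TwoChannelLowRank}}.
#' @param fit output of \code{\link{fitHemodynamics}} on the same data.
#' @return a \code{\linkS4class{LowRankVideo}} of the corrected activity
#' @export
applyCorrection <- function(data, fit) {
  stopifnot(is(data, "TwoChannelLowRank"))
  N <- nPixels(data@gcamp)
  if (length(fit$b) != N || length(fit$t) != N)
    stop("fit covers ", length(fit$b), " pixels but data has ", N)
  Tn <- nTimepoints(data@gcamp)
  U <- cbind(data@gcamp@U, -fit$b * data@hemo@U, fit$t)
  V <- rbind(data@gcamp@V, fit$VhLpf, rep(1, Tn))
  lowRankVideo(U, V, frameRate = data@gcamp@frameRate)
}

#' Mean-adjusted fluorescence (delta-F over F) in low-rank form
#'
#' Maps every pixel trace F to (F - Fbar) / Fbar with Fbar the pixel's
#' temporal mean, by rescaling rows of U and appending one constant
#' component (rank grows by 1). Pixels whose mean fluorescence is within
#' \code{epsF} of zero cannot be normalized; their rows are zeroed and
#' reported.
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}}.
#' @param epsF positive threshold on |Fbar| below which a pixel is masked.
#' @return a \code{\linkS4class{LowRankVideo}} of the dF/F video (the masked
#'   pixel indices are attached as attribute \code{"masked"})
#' @export
dff <- function(lrv, epsF = 1e-6) {
  stopifnot(is(lrv, "LowRankVideo"))
  Fbar <- drop(lrv@U %*% rowMeans(lrv@V))
  masked <- abs(Fbar) <= epsF
  scale <- ifelse(masked, 0, 1 / Fbar)
  if (any(masked))
    message(sum(masked), " pixel(s) with |mean| <= ", epsF,
            " masked in dF/F")
  U <- cbind(scale * lrv@U, ifelse(masked, 0, -1))
  V <- rbind(lrv@V, rep(1, ncol(lrv@V)))
  out <- lowRankVideo(U, V, frameRate = lrv@frameRate)
  attr(out, "masked") <- which(masked)
  out
}
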