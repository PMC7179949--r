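# Readers and writers. Dense videos come in as TIFF stacks (T frames of
# H x W) or headerless CSV matrices (N x T); factored videos and fits are
# stored as directories of full-precision CSV matrices plus a JSON sidecar,
# which round-trip losslessly and keep the repository text-only.

writeMatrixCSV <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x) > 0)
    writeLines(apply(x, 1L, function(r) paste(sprintf("%.17g", r),
                                              collapse = ",")), con)
}

readMatrixCSV <- function(path, ncolHint = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(matrix(0, 0, if (is.null(ncolHint)) 0 else ncolHint))
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Read a video from disk
#'
#' Accepts a TIFF stack (frames of H x W, returned as a dense N x T matrix
#' with pixels flattened row-major to match the atlas convention), a
#' headerless CSV holding a dense N x T matrix, or a directory containing
#' \code{U.csv} and \code{V.csv} (plus optional \code{meta.json} with
#' \code{frameRate}), returned directly as a
#' \code{\linkS4class{LowRankVideo}}.
#'
#' @param path file or directory path.
#' @param frameRate frame rate to attach when the file carries none.
#' @return a dense matrix (with attribute \code{"dims"} = c(H, W)) or a
#'   \code{\linkS4class{LowRankVideo}}
#' @export
readVideo <- function(path, frameRate = NA_real_) {
  if (dir.exists(path)) {
    uf <- file.path(path, "U.csv"); vf <- file.path(path, "V.csv")
    if (!file.exists(uf) || !file.exists(vf))
      stop("factored video directory must contain U.csv and V.csv: ", path)
    U <- readMatrixCSV(uf); V <- readMatrixCSV(vf)
    if (ncol(U) != nrow(V))
      stop("factor shape mismatch: U is ", nrow(U), "x", ncol(U),
           " but V is ", nrow(V), "x", ncol(V))
    mf <- file.path(path, "meta.json")
    if (file.exists(mf)) {
      meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
      if (!is.null(meta$frameRate)) frameRate <- meta$frameRate
    }
    return(lowRankVideo(U, V, frameRate = frameRate))
  }
  if (!file.exists(path)) stop("video file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
    # row-major pixel flattening: transpose each frame before unrolling
    Y <- vapply(frames, function(f) as.numeric(t(f)), numeric(H * W))
    attr(Y, "dims") <- c(H, W)
    return(Y)
  }
  if (ext %in% c("csv", "txt")) {
    return(readMatrixCSV(path))
  }
  stop("unsupported video format: ", ext)
}

#' Write a low-rank video to a directory
#'
#' @param lrv a \code{\linkS4class{LowRankVideo}}.
#' @param path directory to create.
#' @return invisibly, the path
#' @export
writeVideo <- function(lrv, path) {
  stopifnot(is(lrv, "LowRankVideo"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  dir.create(path, showWarnings = FALSE)
  writeMatrixCSV(lrv@U, file.path(path, "U.csv"))
  writeMatrixCSV(lrv@V, file.path(path, "V.csv"))
  jsonlite::write_json(list(frameRate = lrv@frameRate),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a LocaNMF fit to a directory
#'
#' Stores A, B, C, the component-region map, multipliers, per-region counts,
#' diagnostics and configuration as full-precision CSV/JSON; the fit
#' round-trips losslessly through \code{\link{readFit}}.
#'
#' @param fit a \code{\linkS4class{LocaNMFFit}}.
#' @param path directory to create (parent must exist).
#' @return invisibly, the path
#' @export
writeFit <- function(fit, path) {
  stopifnot(is(fit, "LocaNMFFit"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  dir.create(path, showWarnings = FALSE)
  writeMatrixCSV(fit@A, file.path(path, "A.csv"))
  writeMatrixCSV(fit@B, file.path(path, "B.csv"))
  writeMatrixCSV(fit@C, file.path(path, "C.csv"))
  d <- fit@diagnostics
  meta <- list(
    phi = fit@phi, lambdas = fit@lambdas, ranks = fit@ranks,
    regionIds = fit@regionIds,
    diagnostics = list(
      r2ByRegion = d$r2ByRegion,
      locByComponent = d$locByComponent,
      objectiveTrace = d$objectiveTrace,
      itersUsed = d$itersUsed,
      converged = d$converged
    ),
    config = unclass(d$config)
  )
  jsonlite::write_json(meta, file.path(path, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a LocaNMF fit written by \code{\link{writeFit}}
#'
#' @param path fit directory.
#' @return a \code{\linkS4class{LocaNMFFit}}
#' @export
readFit <- function(path) {
  if (!dir.exists(path)) stop("fit directory not found: ", path)
  meta <- jsonlite::read_json(file.path(path, "fit.json"),
                              simplifyVector = TRUE)
  Kd <- length(meta$phi)
  A <- readMatrixCSV(file.path(path, "A.csv"))
  B <- readMatrixCSV(file.path(path, "B.csv"))
  C <- readMatrixCSV(file.path(path, "C.csv"))
  d <- meta$diagnostics
  cfg <- do.call(locaNMFConfig, as.list(meta$config))
  diag <- list(r2ByRegion = as.numeric(d$r2ByRegion),
               locByComponent = as.numeric(d$locByComponent),
               objectiveTrace = as.numeric(d$objectiveTrace),
               itersUsed = as.list(d$itersUsed),
               converged = as.list(d$converged),
               config = cfg)
  new(Class = "LocaNMFFit", A = A, B = B, C = C,
      phi = as.integer(meta$phi), lambdas = as.numeric(meta$lambdas),
      ranks = as.integer(meta$ranks),
      regionIds = as.integer(meta$regionIds), diagnostics = diag)
}

#' Write a CCA map as CSV
#'
#' @param map a \code{\linkS4class{CCAMap}}.
#' @param path output CSV path (regions as header and row names).
#' @return invisibly, the path
#' @export
writeCCAMap <- function(map, path) {
  v <- map@values
  dimnames(v) <- list(map@regionIds, map@regionIds)
  utils::write.csv(v, path)
  invisible(path)
}
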