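#' Build an Atlas from a label image
#'
#' Constructs an \code{\linkS4class{Atlas}} from a 2-D integer label image.
#' Pixels labeled 0 lie outside the field of view and are excluded from the
#' pixel count N; every remaining distinct label becomes a region. Internal
#' region indices are 1..J in increasing order of the original labels, which
#' are preserved in \code{regionIds}. In-FOV pixels are flattened row-major.
#'
#' @param labelImage integer-valued matrix (H x W); nonnegative labels,
#'   0 = outside the field of view.
#' @param names optional data.frame with columns \code{region_id} and
#'   \code{acronym} mapping labels to region names (extra ids are ignored
#'   with a warning).
#' @return an \code{\linkS4class{Atlas}}
#' @examples
#' lab <- matrix(rep(c(1L, 2L), each = 8), 4, 4)
#' atl <- loadAtlas(lab)
#' nRegions(atl)  # 2
#' @export
loadAtlas <- function(labelImage, names = NULL) {
  if (!is.matrix(labelImage))
    stop("labelImage must be a 2-D matrix")
  if (!is.numeric(labelImage) || any(labelImage != round(labelImage)))
    stop("labelImage must contain integer labels")
  if (any(labelImage < 0))
    stop("labelImage labels must be nonnegative")
  lab <- matrix(as.integer(round(labelImage)), nrow(labelImage), ncol(labelImage))
  if (all(lab == 0L))
    stop("empty atlas: label image contains no nonzero region")

  ids <- sort(unique(lab[lab > 0L]))
  coords <- which(lab > 0L, arr.ind = TRUE)
  # row-major flattening of in-FOV pixels
  ord <- order(coords[, 1L], coords[, 2L])
  coords <- coords[ord, , drop = FALSE]
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"
  pixLab <- lab[cbind(coords[, 1L], coords[, 2L])]
  pixRegion <- match(pixLab, ids)

  nms <- rep(NA_character_, length(ids))
  if (!is.null(names)) {
    if (!all(c("region_id", "acronym") %in% colnames(names)))
      stop("names table must have columns region_id and acronym")
    hit <- match(ids, names$region_id)
    nms <- as.character(names$acronym)[hit]
    extra <- setdiff(names$region_id, ids)
    if (length(extra))
      warning("dropping names for region ids absent from the label image: ",
              paste(extra, collapse = ", "))
  }

  new("Atlas", labels = lab, regionIds = as.integer(ids), regionNames = nms,
      pixelCoords = coords, pixelRegion = as.integer(pixRegion))
}

#' Read an atlas label image from a TIFF or CSV file
#'
#' @param path path to a single-plane TIFF (integer labels, possibly stored
#'   as normalized intensities by the writer and rescaled back) or a
#'   headerless CSV of integer labels.
#' @param namesFile optional CSV with columns \code{region_id},
#'   \code{acronym}.
#' @return an \code{\linkS4class{Atlas}}
#' @export
readAtlasImage <- function(path, namesFile = NULL) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    lab <- round(img)
  } else if (ext %in% c("csv", "txt")) {
    lab <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(lab) <- NULL
  } else stop("unsupported atlas format: ", ext)
  nms <- if (!is.null(namesFile)) utils::read.csv(namesFile) else NULL
  loadAtlas(lab, names = nms)
}

#' Per-region Euclidean distance fields
#'
#' Computes the N x J matrix d with d[n, j] the smallest Euclidean distance
#' (in pixel units) from in-FOV pixel n to any pixel of region j; 0 for
#' pixels inside region j. These distances drive the localization penalty in
#' the spatial HALS update. The transform is exact Euclidean (it matches a
#' brute-force pixel-pair minimum).
#'
#' @param atlas an \code{\linkS4class{Atlas}}
#' @return numeric matrix (N x J)
#' @export
distanceFields <- function(atlas) {
  stopifnot(is(atlas, "Atlas"))
  J <- length(atlas@regionIds)
  N <- nrow(atlas@pixelCoords)
  idx <- cbind(atlas@pixelCoords[, 1L], atlas@pixelCoords[, 2L])
  d <- matrix(0, N, J)
  for (j in seq_len(J)) {
    # foreground = everything outside region j; distmap gives the exact
    # Euclidean distance of each foreground pixel to the nearest region pixel
    fg <- matrix(1, nrow(atlas@labels), ncol(atlas@labels))
    fg[atlas@labels == atlas@regionIds[j]] <- 0
    dm <- EBImage::distmap(fg, metric = "euclidean")
    d[, j] <- dm[idx]
  }
  d
}

#' @describeIn nPixels number of in-FOV pixels of an atlas
#' @export
setMethod("nPixels", "Atlas", function(x) nrow(x@pixelCoords))

#' @describeIn nRegions number of regions of an atlas
#' @export
setMethod("nRegions", "Atlas", function(x) length(x@regionIds))

#' @describeIn regionIds original labels of an atlas
#' @export
setMethod("regionIds", "Atlas", function(x) x@regionIds)

#' Region names accessor
#' @param atlas an \code{\linkS4class{Atlas}}
#' @return character vector of length J (NA where unnamed)
#' @export
regionNames <- function(atlas) atlas@regionNames

#' Per-region pixel index lists
#' @param atlas an \code{\linkS4class{Atlas}}
#' @return list of length J of integer vectors of flattened pixel indices
#' @export
regionPixels <- function(atlas) {
  split(seq_len(nPixels(atlas)), factor(atlas@pixelRegion,
                                        levels = seq_len(nRegions(atlas))))
}

setMethod("show", "Atlas", function(object) {
  cat("Atlas:", nrow(object@labels), "x", ncol(object@labels), "image,",
      nPixels(object), "in-FOV pixels,", nRegions(object), "regions\n")
  sz <- tabulate(object@pixelRegion, nbins = nRegions(object))
  cat("  region sizes:", paste(utils::head(sz, 8), collapse = ", "),
      if (nRegions(object) > 8) "..." else "", "\n")
})
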