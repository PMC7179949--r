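#' Number of in-FOV pixels
#' @param x an \code{Atlas} or \code{LowRankVideo}
#' @return integer scalar N
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' Number of atlas regions
#' @param x an \code{Atlas} or \code{LocaNMFFit}
#' @return integer scalar J
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Number of time points
#' @param x a \code{LowRankVideo} or fit object
#' @return integer scalar T
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' Region identifiers
#' @param x an \code{Atlas}, \code{LocaNMFFit} or \code{CCAMap}
#' @return integer vector of original region labels
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' Dense reconstruction
#'
#' Materializes the pixels-by-time product of the factors. Only intended for
#' small problems and tests; all fitting stays in factored form.
#' @param x a \code{LowRankVideo} or \code{SemiNMFFit}
#' @return dense numeric matrix (N x T)
#' @export
setGeneric("reconstruct", function(x) standardGeneric("reconstruct"))

#' Spatial components accessor
#' @param x a \code{SemiNMFFit}
#' @return numeric matrix (N x K)
#' @export
setGeneric("spatialComponents", function(x) standardGeneric("spatialComponents"))

#' Temporal components accessor
#' @param x a \code{SemiNMFFit}
#' @return numeric matrix (K x T)
#' @export
setGeneric("temporalComponents", function(x) standardGeneric("temporalComponents"))

#' Subspace mixing weights accessor
#' @param x a \code{SemiNMFFit}
#' @return numeric matrix (K x Kd)
#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))

#' Component-to-region map accessor
#' @param x a \code{LocaNMFFit}
#' @return integer vector of length K (internal region indices)
#' @export
setGeneric("componentRegions", function(x) standardGeneric("componentRegions"))

#' Fit diagnostics accessor
#' @param x a \code{LocaNMFFit}
#' @return list of diagnostics (see \code{\linkS4class{LocaNMFFit}})
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))
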