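#' Cosine similarity between matrix columns
#'
#' @param X,Y numeric matrices with the same number of rows.
#' @return matrix (ncol(X) x ncol(Y)) of cosine similarities; pairs
#'   involving a zero column get similarity 0 by convention
#' @export
cosineSimilarity <- function(X, Y) {
  nx <- sqrt(colSums(X^2))
  ny <- sqrt(colSums(Y^2))
  S <- crossprod(X, Y)
  S <- S / outer(pmax(nx, .Machine$double.xmin),
                 pmax(ny, .Machine$double.xmin))
  S[nx == 0, ] <- 0
  S[, ny == 0] <- 0
  S
}

#' Greedy matching of components across fits
#'
#' Matches columns of two spatial component matrices by repeatedly pairing
#' the unmatched pair with the highest similarity (cosine by default, or
#' Pearson correlation) until the smaller side is exhausted. Ties break on
#' the lowest reference index, then the lowest other index, making the
#' matching deterministic. Zero columns have similarity 0 to everything.
#'
#' @param ARef reference components (N x K1).
#' @param AOther components to match (N x K2), same pixel indexing.
#' @param metric \code{"cosine"} (default) or \code{"correlation"}.
#' @return list with \code{pairs} (m x 2 matrix of column indices:
#'   reference, other; m = min(K1, K2)) and \code{similarity} (length m,
#'   in matching order)
#' @export
matchComponents <- function(ARef, AOther, metric = c("cosine", "correlation")) {
  metric <- match.arg(metric)
  if (nrow(ARef) != nrow(AOther))
    stop("component matrices must share pixel indexing")
  S <- if (metric == "cosine") cosineSimilarity(ARef, AOther)
       else {
         S0 <- suppressWarnings(stats::cor(ARef, AOther))
         S0[is.na(S0)] <- 0
         S0
       }
  m <- min(ncol(ARef), ncol(AOther))
  pairs <- matrix(0L, m, 2L, dimnames = list(NULL, c("ref", "other")))
  sim <- numeric(m)
  W <- S
  for (i in seq_len(m)) {
    best <- which(W == max(W), arr.ind = TRUE)
    # deterministic tie-break: lowest ref index, then lowest other index
    best <- best[order(best[, 1L], best[, 2L])[1L], , drop = FALSE]
    pairs[i, ] <- c(best[1L], best[2L])
    sim[i] <- S[best[1L], best[2L]]
    W[best[1L], ] <- -Inf
    W[, best[2L]] <- -Inf
  }
  ord <- order(pairs[, 1L])
  list(pairs = pairs[ord, , drop = FALSE], similarity = sim[ord])
}

# first canonical correlation between two multivariate time series
# (rows = variables), computed from the ridge-whitened cross-covariance
firstCanCor <- function(X, Y, ridge = 1e-8) {
  X <- X - rowMeans(X)
  Y <- Y - rowMeans(Y)
  Tn <- ncol(X)
  Sxx <- tcrossprod(X) / Tn + ridge * diag(nrow(X))
  Syy <- tcrossprod(Y) / Tn + ridge * diag(nrow(Y))
  Sxy <- tcrossprod(X, Y) / Tn
  whiten <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, .Machine$double.eps)
    e$vectors %*% (t(e$vectors) / sqrt(vals))
  }
  M <- whiten(Sxx) %*% Sxy %*% whiten(Syy)
  min(max(svd(M, nu = 0, nv = 0)$d[1L], 0), 1)
}

#' Region-pair canonical correlation map
#'
#' For every pair of atlas regions, computes the first canonical correlation
#' between the temporal components assigned to the two regions (components
#' are mean-centered over time; within-region covariances are regularized
#' with a small ridge to handle rank deficiency). The diagonal is 1.
#'
#' @param C temporal components (K x T).
#' @param phi integer vector of length K, internal region index per
#'   component.
#' @param regionIds integer vector of the J region labels.
#' @param ridge ridge added to the within-region covariances; default 1e-8.
#' @return a \code{\linkS4class{CCAMap}}
#' @export
ccaMap <- function(C, phi, regionIds, ridge = 1e-8) {
  J <- length(regionIds)
  if (!all(seq_len(J) %in% phi))
    stop("every region needs at least one component")
  vals <- diag(1, J)
  sets <- lapply(seq_len(J), function(j) C[phi == j, , drop = FALSE])
  cvar <- vapply(sets, function(M) max(apply(M, 1L, stats::var)), 0)
  if (any(cvar == 0))
    warning("constant temporal components in region(s): ",
            paste(regionIds[cvar == 0], collapse = ", "))
  for (i in seq_len(J - 1)) {
    for (j in seq((i + 1), J)) {
      vals[i, j] <- vals[j, i] <- firstCanCor(sets[[i]], sets[[j]], ridge)
    }
  }
  new("CCAMap", values = vals, regionIds = as.integer(regionIds))
}

#' Mean squared difference between two CCA maps
#'
#' The mean of squared elementwise differences over the off-diagonal
#' upper-triangle entries (the informative region pairs).
#'
#' @param map1,map2 \code{\linkS4class{CCAMap}}s over the same regions.
#' @return numeric scalar
#' @export
mapDistance <- function(map1, map2) {
  stopifnot(is(map1, "CCAMap"), is(map2, "CCAMap"))
  if (!identical(map1@regionIds, map2@regionIds))
    stop("CCA maps cover different region sets")
  ut <- upper.tri(map1@values)
  mean((map1@values[ut] - map2@values[ut])^2)
}

#' CCA map of a LocaNMF fit
#'
#' Convenience wrapper: \code{\link{ccaMap}} on the fit's temporal
#' components and region assignment.
#'
#' @param fit a \code{\linkS4class{LocaNMFFit}}.
#' @param ridge ridge passed to \code{\link{ccaMap}}.
#' @return a \code{\linkS4class{CCAMap}}
#' @export
ccaMapOfFit <- function(fit, ridge = 1e-8) {
  ccaMap(fit@C, fit@phi, fit@regionIds, ridge = ridge)
}

#' @describeIn regionIds region labels of a CCA map
#' @export
setMethod("regionIds", "CCAMap", function(x) x@regionIds)

#' Values accessor for a CCA map
#' @param map a \code{\linkS4class{CCAMap}}
#' @return numeric J x J matrix
#' @export
ccaValues <- function(map) map@values

setMethod("show", "CCAMap", function(object) {
  J <- length(object@regionIds)
  ut <- upper.tri(object@values)
  cat("CCAMap:", J, "regions; off-diagonal range [",
      sprintf("%.3f", min(object@values[ut])), ",",
      sprintf("%.3f", max(object@values[ut])), "]\n")
})
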