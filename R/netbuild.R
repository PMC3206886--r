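# Connectivity-matrix construction and fixed-wiring-cost binarization.

#' Interregional Pearson correlation matrix of one subject
#'
#' @param ts a \linkS4class{RoiTimeSeries} with at least 3 timepoints and
#'   no constant region series.
#' @return A \linkS4class{ConnectivityMatrix} (diagonal set to exactly 1).
#' @examples
#' ts <- RoiTimeSeries(rbind(c(1, 2, 3, 4), c(1, 2, 3, 5)), c("a", "b"))
#' corValues(correlationMatrix(ts))["a", "b"]  # 0.9827
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  x <- ts@data
  if (ncol(x) < 3) stop("need at least 3 timepoints")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("constant time series for region(s): ",
         paste(ts@regionLabels[sds == 0], collapse = ", "))
  r <- stats::cor(t(x))
  ConnectivityMatrix(r, ts@regionLabels)
}

# deterministic ranking of the upper-triangle pairs: by value descending,
# ties broken lexicographically on (row, col)
.rankedPairs <- function(r, mode) {
  idx <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[idx]
  key <- if (mode == "absolute") abs(vals) else vals
  ord <- order(-key, idx[, 1], idx[, 2])
  list(idx = idx[ord, , drop = FALSE], vals = vals[ord])
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Retains the \code{round(sparsity * N(N-1)/2)} node pairs with the
#' largest correlations as edges (rounding half away from zero), so
#' networks thresholded at equal sparsity have identical wiring cost.
#' Ranking uses signed correlations by default; an absolute-value mode is
#' available. Ties at the cut rank are broken deterministically by
#' lexicographic (row, column) order. The diagonal is never an edge.
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param sparsity target wiring cost in (0, 1].
#' @param mode \code{"signed"} (default) or \code{"absolute"} ranking.
#' @return A \linkS4class{BinaryGraph} with exactly the target edge count.
#' @examples
#' # N = 90 at 15% sparsity gives round(0.15 * 4005) = 601 edges
#' @export
thresholdBySparsity <- function(cm, sparsity, mode = c("signed", "absolute")) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  mode <- match.arg(mode)
  if (!(sparsity > 0 && sparsity <= 1))
    stop("sparsity must lie in (0, 1]")
  n <- nrow(cm@r)
  npairs <- n * (n - 1) / 2
  k <- .roundHalfUp(sparsity * npairs)
  if (k < 1) stop("sparsity too small: no edges would be retained")
  k <- min(k, npairs)
  ranked <- .rankedPairs(cm@r, mode)
  a <- .adjFromEdges(ranked$idx[seq_len(k), , drop = FALSE], n)
  BinaryGraph(a, cm@regionLabels)
}

#' Threshold a connectivity matrix over a sparsity sweep
#'
#' One binarized graph per sparsity from \code{low} to \code{high}
#' (inclusive) in steps of \code{step}. Because edges are rank-selected
#' with a fixed ordering, the edge set at any sparsity is nested inside
#' the edge set at every larger sparsity.
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param low,high,step sweep definition; defaults 0.15, 0.25, 0.01.
#' @param mode passed to \code{\link{thresholdBySparsity}}.
#' @return Named list of \linkS4class{BinaryGraph}s keyed by sparsity.
#' @export
sweepThresholds <- function(cm, low = 0.15, high = 0.25, step = 0.01,
                            mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (low > high) stop("low must not exceed high")
  if (step <= 0) stop("step must be positive")
  svals <- seq(low, high + step * 1e-8, by = step)
  svals <- round(svals[svals <= high + 1e-12], 10)
  graphs <- lapply(svals, function(s) thresholdBySparsity(cm, s, mode))
  names(graphs) <- formatC(svals, format = "g")
  graphs
}

#' Smallest sparsity giving a fully connected network
#'
#' Scans an ascending candidate list and returns the first sparsity whose
#' binarized graph has no isolated node and forms a single connected
#' component; \code{NA} when no candidate qualifies. This reproduces the
#' selection of the lowest wiring cost at which the cortical networks stay
#' fully connected.
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param candidates ascending numeric vector of sparsities.
#' @param mode passed to \code{\link{thresholdBySparsity}}.
#' @return A single sparsity value, or \code{NA_real_}.
#' @export
minConnectedSparsity <- function(cm, candidates,
                                 mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!length(candidates)) stop("candidate list is empty")
  if (is.unsorted(candidates)) stop("candidates must be ascending")
  for (s in candidates) {
    g <- thresholdBySparsity(cm, s, mode)
    a <- g@adjacency
    if (all(rowSums(a) > 0) && .isConnected(a)) return(s)
  }
  NA_real_
}

#' Fisher z transformation of correlation coefficients
#'
#' \code{z = arctanh(r)}, the variance-stabilizing transform used before
#' group statistics on edge weights. Strictly increasing and odd; defined
#' only for \code{|r| < 1}.
#'
#' @param r numeric vector (or matrix) of correlations with \code{|r| < 1}.
#' @return Transformed values of the same shape.
#' @examples
#' fisherZ(0.5)   # 0.5493
#' fisherZ(-0.5)  # -0.5493
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1))
    stop("fisherZ requires |r| < 1")
  atanh(r)
}
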