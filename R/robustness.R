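# Targeted-attack resilience: remove nodes in decreasing group-mean
# betweenness order and track the decay of the largest connected component.

#' Attack order from group betweenness
#'
#' Ranks nodes by their mean betweenness across subjects, descending; ties
#' are broken by canonical (column) label order. This fixed ranking is the
#' order in which nodes are eliminated during a targeted attack.
#'
#' @param betweennessBySubject subjects x nodes numeric matrix (columns
#'   named by node labels).
#' @return Character vector of node labels (or integer indices when the
#'   matrix has no column names), most central first.
#' @export
attackOrder <- function(betweennessBySubject) {
  b <- as.matrix(betweennessBySubject)
  if (nrow(b) < 1) stop("need at least one subject")
  means <- colMeans(b)
  ord <- order(-means, seq_along(means))
  if (!is.null(colnames(b))) colnames(b)[ord] else ord
}

#' Targeted node-removal attack
#'
#' Removes nodes one at a time in the given order and records, after each
#' removal, the size of the largest connected component divided by the
#' original node count. The curve starts at 1 for a connected graph, is
#' monotone non-increasing (asserted), and stops once the largest
#' component is a single node (or the order is exhausted);
#' \code{stopAtSingleton = FALSE} continues to the full grid, which gives
#' every subject a common removal grid for group comparison.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @param order node labels or indices, most central first; a prefix of
#'   the node set is allowed.
#' @param stopAtSingleton stop once the largest component has one node
#'   (default TRUE).
#' @return data.frame with \code{removed_fraction} and \code{lcc_fraction}.
#' @examples
#' star <- generateFixtureGraph("star", 10)
#' targetedAttack(star, attackOrder(t(betweennessCentrality(star))))
#' @export
targetedAttack <- function(graph, order, stopAtSingleton = TRUE) {
  stopifnot(is(graph, "BinaryGraph"))
  n <- nrow(graph@adjacency)
  if (is.character(order)) {
    idx <- match(order, graph@regionLabels)
    if (anyNA(idx)) stop("node not in graph: ",
                         paste(order[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(order)
    if (any(idx < 1 | idx > n)) stop("node index out of range")
  }
  if (anyDuplicated(idx)) stop("attack order contains duplicate nodes")
  removedFraction <- 0
  lccFraction <- .largestComponentSize(graph@adjacency) / n
  alive <- rep(TRUE, n)
  for (m in seq_along(idx)) {
    alive[idx[m]] <- FALSE
    sub <- graph@adjacency[alive, alive, drop = FALSE]
    lcc <- if (any(alive)) .largestComponentSize(sub) else 0L
    removedFraction <- c(removedFraction, m / n)
    lccFraction <- c(lccFraction, lcc / n)
    if (stopAtSingleton && lcc <= 1L) break
  }
  stopifnot(all(diff(lccFraction) <= 1e-12))  # monotone non-increasing
  data.frame(removed_fraction = removedFraction,
             lcc_fraction = lccFraction)
}

# Welch t-test p-value that tolerates the degenerate zero-variance case
.safeTwoSampleP <- function(xa, xb) {
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
  }
  stats::t.test(xa, xb)$p.value
}

#' Compare robustness curves between two groups
#'
#' At each removal fraction of a common grid, tests the per-subject
#' largest-component fractions of group A against group B (Welch two-sample
#' t-test by default, or a permutation test of the mean difference) and
#' reports the raw p-values plus the longest contiguous run of significant
#' steps.
#'
#' @param groupA,groupB lists of curves from \code{\link{targetedAttack}}
#'   on a common removal grid, at least two subjects per group.
#' @param alpha significance level for the contiguous range (default 0.05).
#' @param method \code{"ttest"} (default) or \code{"permutation"}.
#' @param nPerm permutation count (default 1000).
#' @return data.frame with \code{removed_fraction}, \code{mean_a},
#'   \code{mean_b}, \code{p}, \code{significant}; the longest contiguous
#'   significant run is in \code{attr(, "significantRange")}.
#' @export
compareCurves <- function(groupA, groupB, alpha = 0.05,
                          method = c("ttest", "permutation"), nPerm = 1000) {
  method <- match.arg(method)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need at least two subjects per group to compare curves")
  grid <- groupA[[1]]$removed_fraction
  for (cv in c(groupA, groupB)) {
    if (!isTRUE(all.equal(cv$removed_fraction, grid)))
      stop("curves are not on a common removal grid")
  }
  matA <- vapply(groupA, function(cv) cv$lcc_fraction, numeric(length(grid)))
  matB <- vapply(groupB, function(cv) cv$lcc_fraction, numeric(length(grid)))
  p <- vapply(seq_along(grid), function(i) {
    xa <- matA[i, ]; xb <- matB[i, ]
    if (method == "ttest") return(.safeTwoSampleP(xa, xb))
    obs <- abs(mean(xa) - mean(xb))
    pooled <- c(xa, xb)
    na <- length(xa)
    hits <- 0L
    for (b in seq_len(nPerm)) {
      pick <- sample.int(length(pooled), na)
      if (abs(mean(pooled[pick]) - mean(pooled[-pick])) >= obs - 1e-15)
        hits <- hits + 1L
    }
    (hits + 1) / (nPerm + 1)
  }, numeric(1))
  sig <- p < alpha
  out <- data.frame(removed_fraction = grid,
                    mean_a = rowMeans(matA), mean_b = rowMeans(matB),
                    p = p, significant = sig)
  runs <- rle(sig)
  range <- NULL
  if (any(runs$values)) {
    len <- max(runs$lengths[runs$values])
    pos <- which(runs$values & runs$lengths == len)[1]
    start <- sum(runs$lengths[seq_len(pos - 1)]) + 1
    range <- grid[c(start, start + len - 1)]
  }
  attr(out, "significantRange") <- range
  out
}
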