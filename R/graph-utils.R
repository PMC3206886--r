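# Internal adjacency-matrix graph helpers shared across modules.

# round half away from zero (edge-count rounding rule)
.roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

.adjList <- function(a) {
  lapply(seq_len(nrow(a)), function(i) which(a[i, ] > 0))
}

.edgeList <- function(a) {
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

.adjFromEdges <- function(edges, n) {
  a <- matrix(0, n, n)
  if (nrow(edges)) {
    a[edges] <- 1
    a[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  a
}

# component membership via breadth-first search
.components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(a[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

.isConnected <- function(a) {
  nrow(a) == 0L || all(.components(a) == 1L)
}

.largestComponentSize <- function(a) {
  if (nrow(a) == 0L) return(0L)
  max(tabulate(.components(a)))
}

.clusteringAdj <- function(a) {
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a)
  mean(ifelse(k < 2, 0, tri / (k * (k - 1))))
}

.cplAdj <- function(a) {
  d <- .allPairsDistances(a)
  up <- d[upper.tri(d)]
  if (any(is.infinite(up)))
    stop("graph is disconnected: characteristic path length undefined")
  mean(up)
}

# all-pairs unweighted shortest-path distances by repeated boolean
# matrix products; Inf marks unreachable pairs
.allPairsDistances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  reach <- a > 0
  k <- 1L
  while (any(is.infinite(d)) && k < n) {
    reach <- (reach %*% a) > 0
    newly <- reach & is.infinite(d)
    if (!any(newly)) break
    k <- k + 1L
    d[newly] <- k
  }
  d
}
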