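# Independent brute-force oracles for the graph metrics, deliberately
# implemented with different algorithms than the package (Floyd-Warshall
# distances, explicit shortest-path enumeration, direct triangle counts).

oracleDistances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
  d
}

# betweenness by exhaustive enumeration of all shortest paths
oracleBetweenness <- function(a) {
  n <- nrow(a)
  d <- oracleDistances(a)
  b <- numeric(n)
  enum <- function(cur, target) {
    if (cur == target) return(list(integer(0)))
    out <- list()
    for (u in which(a[cur, ] > 0)) {
      if (is.finite(d[u, target]) && d[u, target] == d[cur, target] - 1) {
        for (p in enum(u, target)) out <- c(out, list(c(u, p)))
      }
    }
    out
  }
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (!is.finite(d[j, k])) next
    paths <- enum(j, k)
    npaths <- length(paths)
    for (p in paths) {
      for (i in setdiff(p, k)) b[i] <- b[i] + 1 / npaths
    }
  }
  b
}

# per-node clustering by direct neighbour-pair counting
oracleClustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(a[t(pairs)] > 0)
  }, numeric(1))
}

randomAdjacency <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up[stats::runif(length(up)) < p]] <- 1
  a + t(a)
}

randomConnectedGraph <- function(n, p) {
  repeat {
    a <- randomAdjacency(n, p)
    d <- oracleDistances(a)
    if (all(is.finite(d))) return(BinaryGraph(a))
  }
}

smallCohortConfig <- function(...) {
  cohortConfig(nFemalePerGroup = 3, nMalePerGroup = 3, nRegions = 40,
               nTimepoints = 80, nModules = 8, ...)
}
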