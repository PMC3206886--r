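# Small-world metrics, betweenness centrality and degree-preserving null
# ensembles -- the quantitative core of the network analysis.

#' Per-node clustering coefficients
#'
#' For node i with degree \eqn{k_i} and \eqn{E_i} edges among its
#' neighbors, \eqn{C_i = 2 E_i / (k_i (k_i - 1))}: the proportion of
#' possible connections that actually exist between the nearest neighbors.
#' Nodes with fewer than two neighbors get \eqn{C_i = 0} (kept in the
#' network average, which keeps the global coefficient defined at sparse
#' wiring costs).
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @param node optional single node (label or index) to return; default all.
#' @return Named numeric vector of \eqn{C_i} in [0, 1] (or one value).
#' @examples
#' tri <- generateFixtureGraph("complete", 3)
#' nodalClustering(tri)  # all 1
#' @export
nodalClustering <- function(graph, node = NULL) {
  stopifnot(is(graph, "BinaryGraph"))
  a <- graph@adjacency
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a)  # 2 * edges among neighbors
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  names(ci) <- graph@regionLabels
  if (!is.null(node)) {
    if (is.character(node)) {
      if (!node %in% graph@regionLabels) stop("unknown node: ", node)
      return(ci[[node]])
    }
    if (node < 1 || node > length(ci)) stop("unknown node index: ", node)
    return(ci[[node]])
  }
  ci
}

#' Network clustering coefficient
#'
#' Arithmetic mean of the per-node clustering coefficients over all nodes.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @return C in [0, 1].
#' @export
networkClustering <- function(graph) {
  mean(nodalClustering(graph))
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path distance (edge count) over all unordered
#' node pairs. Defined only for connected graphs; a disconnected input is
#' an explicit error rather than a silent infinite or harmonic-mean
#' substitute.
#'
#' @param graph a connected \linkS4class{BinaryGraph}.
#' @return L (at least 1 for graphs with two or more nodes).
#' @examples
#' characteristicPathLength(generateFixtureGraph("path", 4))  # 5/3
#' @export
characteristicPathLength <- function(graph) {
  stopifnot(is(graph, "BinaryGraph"))
  d <- .allPairsDistances(graph@adjacency)
  up <- d[upper.tri(d)]
  if (any(is.infinite(up)))
    stop("graph is disconnected: characteristic path length undefined")
  mean(up)
}

#' Betweenness centrality (unnormalized)
#'
#' For node i, \eqn{B_i = \sum_{j \ne k \ne i} n_{jk}(i) / n_{jk}} over
#' unordered pairs, where \eqn{n_{jk}} counts shortest j-k paths and
#' \eqn{n_{jk}(i)} those passing through i as an interior node. Computed
#' with Brandes' accumulation algorithm; reported as raw pair counts (no
#' normalization), the scale on which nodal centrality is compared across
#' groups.
#'
#' @param graph a connected \linkS4class{BinaryGraph}.
#' @return Named numeric vector of \eqn{B_i \ge 0}.
#' @examples
#' betweennessCentrality(generateFixtureGraph("star", 5))  # center: 6
#' @export
betweennessCentrality <- function(graph) {
  stopifnot(is(graph, "BinaryGraph"))
  a <- graph@adjacency
  if (!.isConnected(a))
    stop("graph is disconnected: betweenness undefined on the whole node set")
  n <- nrow(a)
  adjList <- .adjList(a)
  b <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    visited <- integer(n); nv <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      nv <- nv + 1L; visited[nv] <- v
      for (w in adjList[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(nv))) {
      w <- visited[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) b[w] <- b[w] + delta[w]
    }
  }
  b <- b / 2  # undirected: each unordered pair was accumulated twice
  names(b) <- graph@regionLabels
  b
}

#' Degree-preserving randomization (double-edge swaps)
#'
#' Randomizes a graph by repeated double-edge swaps, destroying local
#' (neighborhood) structure while keeping every node's degree exactly.
#' Swaps that would introduce self-loops or multi-edges are rejected, and
#' by default swaps that disconnect the graph are rejected and resampled
#' so the characteristic path length of the null stays defined.
#'
#' @param graph a \linkS4class{BinaryGraph}.
#' @param nSwapsPerEdge successful swaps per edge (default 10).
#' @param seed optional RNG seed.
#' @param keepConnected reject disconnecting swaps (default TRUE).
#' @return A rewired \linkS4class{BinaryGraph} with the identical degree
#'   sequence (asserted on every call).
#' @export
rewirePreservingDegree <- function(graph, nSwapsPerEdge = 10, seed = NULL,
                                   keepConnected = TRUE) {
  stopifnot(is(graph, "BinaryGraph"))
  a <- graph@adjacency
  edges <- .edgeList(a)
  m <- nrow(edges)
  if (m < 2) stop("graph has too few edges to rewire")
  target <- nSwapsPerEdge * m
  run <- function() .rewireEdgesCpp(matrix(as.integer(edges), ncol = 2),
                                    nrow(a), target, keepConnected, 200)
  newEdges <- if (!is.null(seed)) withr::with_seed(as.integer(seed), run())
              else run()
  out <- BinaryGraph(.adjFromEdges(newEdges, nrow(a)), graph@regionLabels)
  stopifnot(identical(sort(rowSums(out@adjacency)), sort(rowSums(a))))
  out
}

#' Small-world metrics against a degree-preserving null ensemble
#'
#' Computes the network clustering coefficient C and characteristic path
#' length L, the means of the same quantities over \code{nRandom}
#' degree-preserving rewired null graphs, and the ratios
#' \eqn{\gamma = C / C_{rand}}, \eqn{\lambda = L / L_{rand}} and the
#' small-worldness scalar \eqn{\sigma = \gamma / \lambda}. A small-world
#' network combines higher-than-random clustering with near-random path
#' length, giving \eqn{\sigma > 1}.
#'
#' @param graph a connected \linkS4class{BinaryGraph}.
#' @param nRandom null-ensemble size (default 100).
#' @param seed optional RNG seed governing the whole ensemble.
#' @param nSwapsPerEdge rewiring effort per null graph (default 10).
#' @return List with elements \code{C}, \code{L}, \code{Crand},
#'   \code{Lrand}, \code{gamma}, \code{lambda}, \code{sigma} and
#'   \code{ensemble} (data.frame of per-realization C and L).
#' @examples
#' \donttest{
#' g <- generateFixtureGraph("watts_strogatz", 90, k = 12, p = 0.1, seed = 1)
#' smallWorldMetrics(g, nRandom = 20, seed = 1)$sigma  # > 1
#' }
#' @export
smallWorldMetrics <- function(graph, nRandom = 100, seed = NULL,
                              nSwapsPerEdge = 10) {
  stopifnot(is(graph, "BinaryGraph"))
  cObs <- networkClustering(graph)
  lObs <- characteristicPathLength(graph)
  a <- graph@adjacency
  n <- nrow(a)
  edges <- matrix(as.integer(.edgeList(a)), ncol = 2)
  degSorted <- sort(unname(rowSums(a)))
  run <- function() {
    cr <- numeric(nRandom); lr <- numeric(nRandom)
    for (i in seq_len(nRandom)) {
      ne <- .rewireEdgesCpp(edges, n, nSwapsPerEdge * nrow(edges), TRUE, 200)
      a2 <- .adjFromEdges(ne, n)
      stopifnot(identical(sort(rowSums(a2)), degSorted))
      cr[i] <- .clusteringAdj(a2)
      lr[i] <- .cplAdj(a2)
    }
    data.frame(C = cr, L = lr)
  }
  ens <- if (!is.null(seed)) withr::with_seed(as.integer(seed), run())
         else run()
  crand <- mean(ens$C); lrand <- mean(ens$L)
  gamma <- cObs / crand
  lambda <- lObs / lrand
  list(C = cObs, L = lObs, Crand = crand, Lrand = lrand,
       gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       ensemble = ens)
}
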