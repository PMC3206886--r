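# Deterministic and seeded graph fixtures used to exercise the network
# metrics on topologies with known properties.

.ringLatticeEdges <- function(n, k) {
  if (k %% 2 != 0 || k >= n)
    stop("ring lattice needs even k with k < n")
  edges <- do.call(rbind, lapply(seq_len(k / 2), function(h) {
    cbind(seq_len(n), ((seq_len(n) + h - 1L) %% n) + 1L)
  }))
  t(apply(edges, 1, sort))
}

#' Generate a fixture graph of a named topology
#'
#' Builds canonical test graphs: ring lattices, Watts-Strogatz small-world
#' graphs (lattice plus random edge rewiring), Erdos-Renyi random graphs,
#' stars, paths, cycles and complete graphs. Deterministic kinds ignore the
#' seed; random kinds are reproducible under it.
#'
#' @param kind one of \code{"ring_lattice"}, \code{"watts_strogatz"},
#'   \code{"erdos_renyi"}, \code{"star"}, \code{"path"}, \code{"cycle"},
#'   \code{"complete"}.
#' @param nNodes number of nodes (at least 2).
#' @param k even lattice degree (ring lattice / Watts-Strogatz).
#' @param p rewiring probability (Watts-Strogatz) or edge probability
#'   (Erdos-Renyi when \code{nEdges} is NULL).
#' @param nEdges exact edge count for Erdos-Renyi (overrides \code{p}).
#' @param seed RNG seed for the random kinds.
#' @param connected for random kinds, resample until the graph is connected.
#' @return A \linkS4class{BinaryGraph}.
#' @examples
#' edgeCount(generateFixtureGraph("complete", 5))       # 10
#' degrees(generateFixtureGraph("star", 5))             # 4, 1, 1, 1, 1
#' @export
generateFixtureGraph <- function(kind, nNodes, k = 4, p = 0.1, nEdges = NULL,
                                 seed = NULL, connected = TRUE) {
  if (nNodes < 2) stop("need at least 2 nodes")
  kind <- match.arg(kind, c("ring_lattice", "watts_strogatz", "erdos_renyi",
                            "star", "path", "cycle", "complete"))
  build <- function() {
    edges <- switch(kind,
      ring_lattice = .ringLatticeEdges(nNodes, k),
      watts_strogatz = {
        e <- .ringLatticeEdges(nNodes, k)
        a <- .adjFromEdges(e, nNodes)
        for (i in seq_len(nrow(e))) {
          if (stats::runif(1) < p) {
            u <- e[i, 1]
            cand <- which(a[u, ] == 0)
            cand <- setdiff(cand, u)
            if (length(cand)) {
              v <- cand[sample.int(length(cand), 1)]
              a[e[i, 1], e[i, 2]] <- a[e[i, 2], e[i, 1]] <- 0
              a[u, v] <- a[v, u] <- 1
            }
          }
        }
        .edgeList(a)
      },
      erdos_renyi = {
        pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
        if (!is.null(nEdges)) {
          if (nEdges < 1 || nEdges > nrow(pairs))
            stop("nEdges out of range")
          pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
        } else {
          pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
        }
      },
      star = cbind(1L, 2:nNodes),
      path = cbind(seq_len(nNodes - 1), 2:nNodes),
      cycle = rbind(cbind(seq_len(nNodes - 1), 2:nNodes), c(1L, nNodes)),
      complete = which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE))
    .adjFromEdges(as.matrix(edges), nNodes)
  }
  random <- kind %in% c("watts_strogatz", "erdos_renyi")
  make <- function() {
    a <- build()
    if (random && connected) {
      tries <- 0
      while (!.isConnected(a)) {
        tries <- tries + 1
        if (tries > 100) stop("could not generate a connected graph")
        a <- build()
      }
    }
    a
  }
  a <- if (random && !is.null(seed)) withr::with_seed(as.integer(seed), make())
       else make()
  BinaryGraph(a)
}
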