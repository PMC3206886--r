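#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// early-exit BFS over neighbor lists: is `target` reachable from `from`?
static bool reachable(const std::vector<std::vector<int> > &nbr,
                      int from, int target,
                      std::vector<int> &queue, std::vector<char> &seen) {
    if (from == target) return true;
    std::fill(seen.begin(), seen.end(), 0);
    int head = 0, tail = 0;
    queue[tail++] = from;
    seen[from] = 1;
    while (head < tail) {
        int v = queue[head++];
        const std::vector<int> &nb = nbr[v];
        for (size_t i = 0; i < nb.size(); ++i) {
            int w = nb[i];
            if (!seen[w]) {
                if (w == target) return true;
                seen[w] = 1;
                queue[tail++] = w;
            }
        }
    }
    return false;
}

static inline void dropNeighbor(std::vector<int> &nb, int v) {
    nb.erase(std::find(nb.begin(), nb.end(), v));
}

// Degree-preserving randomization by double-edge swaps (Maslov-Sneppen).
// edges: m x 2 matrix of 1-based endpoints of an undirected simple graph.
// Performs `targetSwaps` successful swaps; swaps creating self-loops or
// multi-edges are rejected, and (optionally) swaps that disconnect the
// graph are rejected and resampled. Uses R's RNG.
// [[Rcpp::export(".rewireEdgesCpp")]]
IntegerMatrix rewireEdgesCpp(IntegerMatrix edges, int nNodes,
                             double targetSwaps, bool keepConnected,
                             double maxAttemptFactor) {
    int m = edges.nrow();
    if (m < 2) stop("graph has too few edges to rewire");
    std::vector<std::vector<char> > adj(nNodes,
                                        std::vector<char>(nNodes, 0));
    std::vector<std::vector<int> > nbr(nNodes);
    std::vector<int> ea(m), eb(m);
    for (int e = 0; e < m; ++e) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        ea[e] = a; eb[e] = b;
        adj[a][b] = 1; adj[b][a] = 1;
        nbr[a].push_back(b); nbr[b].push_back(a);
    }
    std::vector<int> queue(nNodes);
    std::vector<char> seen(nNodes);
    double attempts = 0,
           maxAttempts = maxAttemptFactor * targetSwaps + 100.0;
    double done = 0;
    while (done < targetSwaps) {
        if (++attempts > maxAttempts)
            stop("graph too small or rigid to rewire: swap attempts exhausted");
        int e1 = (int)(unif_rand() * m);
        int e2 = (int)(unif_rand() * m);
        if (e1 == e2) continue;
        int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
        if (unif_rand() < 0.5) std::swap(c, d);
        // propose replacing a-b, c-d with a-d, c-b
        if (a == c || a == d || b == c || b == d) continue;
        if (adj[a][d] || adj[c][b]) continue;
        adj[a][b] = adj[b][a] = 0;
        adj[c][d] = adj[d][c] = 0;
        adj[a][d] = adj[d][a] = 1;
        adj[c][b] = adj[b][c] = 1;
        dropNeighbor(nbr[a], b); dropNeighbor(nbr[b], a);
        dropNeighbor(nbr[c], d); dropNeighbor(nbr[d], c);
        nbr[a].push_back(d); nbr[d].push_back(a);
        nbr[c].push_back(b); nbr[b].push_back(c);
        if (keepConnected) {
            // only the removed pairs can have been disconnected
            bool ok = reachable(nbr, a, b, queue, seen) &&
                      reachable(nbr, c, d, queue, seen);
            if (!ok) {
                adj[a][d] = adj[d][a] = 0;
                adj[c][b] = adj[b][c] = 0;
                adj[a][b] = adj[b][a] = 1;
                adj[c][d] = adj[d][c] = 1;
                dropNeighbor(nbr[a], d); dropNeighbor(nbr[d], a);
                dropNeighbor(nbr[c], b); dropNeighbor(nbr[b], c);
                nbr[a].push_back(b); nbr[b].push_back(a);
                nbr[c].push_back(d); nbr[d].push_back(c);
                continue;
            }
        }
        eb[e1] = d; ea[e2] = c; eb[e2] = b;
        done += 1;
    }
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) {
        out(e, 0) = std::min(ea[e], eb[e]) + 1;
        out(e, 1) = std::max(ea[e], eb[e]) + 1;
    }
    return out;
}
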