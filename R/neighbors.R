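# Exact k-nearest-neighbor graph construction. Brute-force all-pairs
# Euclidean distances, computed in row blocks to bound memory; exactness and
# the stated tie rule (lower cell-id index wins) are part of the contract, so
# no approximate search library is used.

#' Build an exact k-nearest-neighbor graph from an embedding
#'
#' Self is excluded. Distance ties are broken toward the lower cell-id index
#' (input order). The graph is directed (`symmetric = FALSE`); use
#' [symmetrize_graph()] for the undirected view used by connectivity-style
#' metrics.
#'
#' @param emb An [embedding_set()].
#' @param k number of neighbors, `1 <= k < n_cells`.
#' @param metric only `"euclidean"` is supported.
#' @param block_size rows per distance block (memory knob).
#' @return A `NeighborGraph`: list with `n_nodes`, `k`, `idx` (n x k integer
#'   matrix of neighbor indices), `dist` (n x k distances), `cell_ids`,
#'   `symmetric`.
#' @export
build_neighbor_graph <- function(emb, k, metric = "euclidean",
                                 block_size = 1000L) {
  stopifnot(inherits(emb, "EmbeddingSet"))
  metric <- match.arg(metric, "euclidean")
  n <- nrow(emb$matrix)
  assert_that(k >= 1 && k < n, "k must satisfy 1 <= k < n_cells")
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  X <- emb$matrix
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    D <- cross_dist(X[rows, , drop = FALSE], X)
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- D[r, ]
      d[i] <- Inf
      # order() with index tiebreak implements "lower cell-id wins"
      o <- order(d, seq_len(n))[seq_len(k)]
      idx[i, ] <- o
      dst[i, ] <- d[o]
    }
  }
  structure(list(n_nodes = n, k = k, idx = idx, dist = dst,
                 cell_ids = emb$cell_ids, symmetric = FALSE),
            class = "NeighborGraph")
}

#' Undirected igraph view of a NeighborGraph
#'
#' Edges are the union of directed kNN edges (mutual edges collapsed).
#'
#' @param graph A `NeighborGraph` from [build_neighbor_graph()].
#' @return An [igraph::graph] object with `n_nodes` vertices.
#' @export
symmetrize_graph <- function(graph) {
  stopifnot(inherits(graph, "NeighborGraph"))
  edges <- cbind(rep(seq_len(graph$n_nodes), times = graph$k),
                 as.vector(graph$idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < graph$n_nodes) {
    g <- igraph::add_vertices(g, graph$n_nodes - igraph::vcount(g))
  }
  g
}
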