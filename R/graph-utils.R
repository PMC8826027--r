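# Internal graph helpers shared by the complex-discovery algorithms.
#
# All algorithms operate on a plain adjacency list (a named list of sorted
# character vectors) derived from an igraph object. This keeps iteration
# order fully deterministic: nodes are held in lexicographic order and all
# tie-breaks fall back on identifier order.

# igraph (undirected, simple, named) -> named adjacency list, nodes and
# neighbour vectors sorted lexicographically.
adj_from_graph <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  nodes <- sort(igraph::V(graph)$name)
  al <- igraph::as_adj_list(graph, mode = "all")
  names(al) <- igraph::V(graph)$name
  adj <- lapply(al, function(vs) sort(unique(names(vs))))
  # drop any self references defensively; inputs are expected simple
  adj <- mapply(function(nm, nb) setdiff(nb, nm), names(adj), adj,
                SIMPLIFY = FALSE)
  adj[nodes]
}

# number of edges among `nodes` in the adjacency list
edges_within <- function(adj, nodes) {
  if (length(nodes) < 2L) return(0L)
  deg <- vapply(nodes, function(v) sum(adj[[v]] %in% nodes), integer(1))
  as.integer(sum(deg) / 2L)
}

# density of the induced subgraph; single node has density 1 by convention
subgraph_density <- function(adj, nodes) {
  n <- length(nodes)
  if (n <= 1L) return(1.0)
  2 * edges_within(adj, nodes) / (n * (n - 1))
}

# number of edges between vertex v and the set `nodes`
edges_into <- function(adj, v, nodes) {
  sum(adj[[v]] %in% nodes)
}

neighbours_of_set <- function(adj, nodes) {
  nb <- unique(unlist(adj[nodes], use.names = FALSE))
  sort(setdiff(nb, nodes))
}

is_connected_subset <- function(adj, nodes) {
  n <- length(nodes)
  if (n <= 1L) return(TRUE)
  seen <- nodes[1L]
  frontier <- nodes[1L]
  while (length(frontier) > 0L) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier], use.names = FALSE)),
                             nodes), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

# diameter of the induced subgraph via BFS from every vertex; Inf when the
# subgraph is disconnected
subgraph_diameter <- function(adj, nodes) {
  n <- length(nodes)
  if (n <= 1L) return(0L)
  ecc <- vapply(nodes, function(src) {
    dist <- stats::setNames(rep(Inf, n), nodes)
    dist[src] <- 0
    frontier <- src
    d <- 0
    while (length(frontier) > 0L) {
      d <- d + 1
      nxt <- setdiff(intersect(unique(unlist(adj[frontier], use.names = FALSE)),
                               nodes), names(dist)[is.finite(dist)])
      dist[nxt] <- d
      frontier <- nxt
    }
    max(dist)
  }, numeric(1))
  max(ecc)
}

# Common-neighbour edge weights and derived node weights (DPClus/IPCA).
# Returns list(node_weight = named numeric, degree = named integer).
common_neighbour_weights <- function(adj) {
  nodes <- names(adj)
  nw <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    for (u in adj[[v]]) {
      if (u > v) {
        w <- length(intersect(adj[[v]], adj[[u]]))
        nw[v] <- nw[v] + w
        nw[u] <- nw[u] + w
      }
    }
  }
  deg <- vapply(adj, length, integer(1))
  list(node_weight = nw, degree = deg)
}

# Canonical tie-break ordering: weight desc, degree desc, identifier asc.
order_by_weight <- function(ids, weight, degree) {
  ids[order(-weight[ids], -degree[ids], ids, method = "radix")]
}

# 0/1 adjacency matrix with lexicographically sorted row/column names.
adj_matrix_from_graph <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) {
    return(matrix(0, 0, 0, dimnames = list(character(0), character(0))))
  }
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  nodes <- sort(igraph::V(graph)$name)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, type = "both"))
  A <- A[nodes, nodes, drop = FALSE]
  A[A > 1] <- 1
  diag(A) <- 0
  storage.mode(A) <- "double"
  A
}

# Common-neighbour node weights on an adjacency matrix:
# w(u,v) = |N(u) n N(v)| for each edge, node weight = sum over incident
# edges. (A %*% A) counts common neighbours for every pair; masking by A
# restricts to edges.
cn_node_weights <- function(A) {
  W <- (A %*% A) * A
  rowSums(W)
}
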