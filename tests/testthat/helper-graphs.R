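# Named test graphs (all vertices named; all graphs simple, undirected).

named_graph <- function(edges, isolates = character(0)) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (length(isolates) > 0) g <- igraph::add_vertices(g, length(isolates),
                                                      name = isolates)
  g
}

clique_graph <- function(nodes) {
  named_graph(t(utils::combn(nodes, 2)))
}

clique_edges <- function(nodes) t(utils::combn(nodes, 2))

# two cliques joined by a single bridge edge
bridged_cliques <- function(a_nodes, b_nodes) {
  named_graph(rbind(clique_edges(a_nodes), clique_edges(b_nodes),
                    c(a_nodes[1], b_nodes[1])))
}

# two cliques sharing one vertex
shared_vertex_cliques <- function(a_nodes, b_nodes) {
  named_graph(rbind(clique_edges(a_nodes), clique_edges(b_nodes)))
}

star_graph <- function(n) {
  centre <- "c0"
  leaves <- paste0("v", seq_len(n - 1))
  named_graph(cbind(centre, leaves))
}

path_graph <- function(n) {
  nodes <- sprintf("p%02d", seq_len(n))
  named_graph(cbind(nodes[-n], nodes[-1]))
}

edgeless_graph <- function(n) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  igraph::add_vertices(g, n, name = paste0("z", seq_len(n)))
}

# deterministic pseudo-random simple graph on named nodes
random_named_graph <- function(n, p, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  set.seed(seed)
  keep <- stats::runif(nrow(pairs)) < p
  named_graph(pairs[keep, , drop = FALSE],
              isolates = setdiff(nodes, unique(as.vector(pairs[keep, ]))))
}

# the small fixture suite used for predicate/determinism checks
fixture_graphs <- function() {
  list(
    k5 = clique_graph(paste0("a", 1:5)),
    k5_isolates = igraph::add_vertices(clique_graph(paste0("a", 1:5)), 3,
                                       name = c("x", "y", "z")),
    bridged_k4 = bridged_cliques(paste0("a", 1:4), paste0("b", 1:4)),
    bridged_k5 = bridged_cliques(paste0("a", 1:5), paste0("b", 1:5)),
    shared_k4 = shared_vertex_cliques(c("s0", paste0("a", 1:3)),
                                      c("s0", paste0("b", 1:3))),
    star6 = star_graph(6),
    path8 = path_graph(8),
    overlap_k4_k5 = shared_vertex_cliques(c("o1", "o2", paste0("a", 1:2)),
                                          c("o1", "o2", paste0("b", 1:3))),
    random10 = random_named_graph(10, 0.35, seed = 11),
    edgeless = edgeless_graph(4))
}
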