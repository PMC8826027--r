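# Independent oracles, deliberately naive implementations kept separate
# from the package's code paths.

# adjacency list straight from igraph, for oracle-side computations
oracle_adj <- function(graph) {
  al <- igraph::as_adj_list(graph, mode = "all")
  names(al) <- igraph::V(graph)$name
  lapply(al, function(vs) sort(unique(names(vs))))
}

oracle_density <- function(graph, nodes) {
  n <- length(nodes)
  if (n <= 1) return(1)
  sub <- igraph::induced_subgraph(graph, nodes)
  2 * igraph::ecount(sub) / (n * (n - 1))
}

oracle_connected <- function(graph, nodes) {
  igraph::is_connected(igraph::induced_subgraph(graph, nodes))
}

oracle_diameter <- function(graph, nodes) {
  sub <- igraph::induced_subgraph(graph, nodes)
  if (!igraph::is_connected(sub)) return(Inf)
  igraph::diameter(sub, unconnected = FALSE)
}

# every connected vertex subset of size <= max_size (exhaustive; for
# graphs of <= ~10 nodes only)
enumerate_connected_subsets <- function(graph, max_size) {
  nodes <- igraph::V(graph)$name
  out <- list()
  for (s in seq_len(max_size)) {
    if (s > length(nodes)) break
    for (idx in utils::combn(length(nodes), s, simplify = FALSE)) {
      sub <- nodes[idx]
      if (oracle_connected(graph, sub)) out[[length(out) + 1]] <- sub
    }
  }
  out
}

# brute-force neighbourhood affinity
oracle_na <- function(a, b) length(intersect(a, b))^2 / (length(a) * length(b))

# brute-force pairwise AUC: fraction of positive-negative pairs ranked
# correctly, ties counting one half
oracle_pair_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# naive line-by-line set-based edge-list parser (io oracle)
oracle_parse_edgelist <- function(path) {
  lines <- readLines(path)
  seen <- character(0)
  nodes <- character(0)
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (f[1] == f[2]) next
    key <- paste(sort(f[1:2]), collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      nodes <- union(nodes, f[1:2])
    }
  }
  list(nodes = sort(nodes), edges = sort(seen))
}

graph_edge_keys <- function(graph) {
  el <- igraph::as_edgelist(graph)
  sort(apply(el, 1, function(e) paste(sort(e), collapse = "|")))
}

# random clustering over a gene universe
random_clustering <- function(genes, n_clusters, size_range, seed,
                              prefix = "rc") {
  set.seed(seed)
  cl <- lapply(seq_len(n_clusters), function(i) {
    sample(genes, sample(size_range[1]:size_range[2], 1))
  })
  names(cl) <- paste0(prefix, seq_len(n_clusters))
  clustering(cl, algorithm = prefix)
}

# relabel a graph's vertex names via a named map
relabel_graph <- function(graph, map) {
  igraph::set_vertex_attr(graph, "name",
                          value = unname(map[igraph::V(graph)$name]))
}

clusters_as_set <- function(clustering) {
  unname(lapply(clustering$clusters, sort))
}
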