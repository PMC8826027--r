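#' IPCA: small-diameter cluster growth
#'
#' A modification of DPClus that computes common-neighbour node weights
#' exactly once on the input graph and reuses them throughout, and that
#' constrains clusters by diameter instead of density. Clusters are grown
#' from the highest-weight seed not yet assigned to a cluster; a
#' neighbouring vertex `v` is admitted when its interaction probability
#' `IP(v) = |edges(v, cluster)| / |cluster|` is at least `t_in` and the
#' extended cluster's diameter does not exceed `d_max`. Emitted members
#' are removed from the seed queue only, never from the graph, so later
#' clusters may overlap earlier ones.
#'
#' @inheritParams mcode
#' @param t_in minimum interaction probability for admission
#'   (default 0.5).
#' @param d_max maximum cluster diameter (default 2).
#' @param min_size minimum emitted cluster size (default 2).
#' @return a [clustering()] with algorithm tag `"ipca"`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' ipca(g)
#' @export
ipca <- function(graph, t_in = 0.5, d_max = 2, min_size = 2) {
  stopifnot(t_in >= 0, t_in <= 1, d_max >= 1, min_size >= 1)
  params <- list(t_in = t_in, d_max = d_max, min_size = min_size)
  adj <- adj_from_graph(graph)
  A <- adj_matrix_from_graph(graph)
  nodes <- rownames(A)
  if (length(nodes) == 0L) {
    return(clustering(list(), algorithm = "ipca", params = params))
  }
  nw <- cn_node_weights(A)
  deg <- rowSums(A)
  queue <- order_by_weight(nodes, nw, deg)
  in_cluster <- stats::setNames(rep(FALSE, length(nodes)), nodes)

  out <- list()
  for (seed in queue) {
    if (in_cluster[seed]) next
    members <- ipca_grow(adj, A, nw, seed, t_in, d_max)
    if (length(members) >= min_size) {
      out[[length(out) + 1L]] <- members
      in_cluster[members] <- TRUE
    } else {
      in_cluster[seed] <- TRUE
    }
  }
  clustering(out, algorithm = "ipca", params = params)
}

ipca_grow <- function(adj, A, nw, seed, t_in, d_max) {
  nodes <- rownames(A)
  members <- seed
  repeat {
    k_into <- colSums(A[members, , drop = FALSE])
    k_into[members] <- 0
    cand <- nodes[k_into > 0]
    if (length(cand) == 0L) break
    cand <- cand[order(-k_into[cand], -nw[cand], cand, method = "radix")]
    added <- FALSE
    for (v in cand) {
      ip <- k_into[v] / length(members)
      if (ip >= t_in &&
          subgraph_diameter(adj, c(members, v)) <= d_max) {
        members <- c(members, v)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  members
}
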