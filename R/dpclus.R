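#' DPClus: density-periphery cluster growth
#'
#' Iterative complex discovery driven by common-neighbour weights. Each
#' edge `{u,v}` is weighted by the number of common neighbours of `u` and
#' `v`; a node's weight is the sum of its incident edge weights. A cluster
#' is seeded at the highest-weight node and extended greedily: candidate
#' neighbours are ranked by (edges into the cluster, node weight,
#' identifier) and the best candidate is admitted while the extended
#' cluster's density stays at least `d_min` and the candidate's cluster
#' property `cp(v) = |edges(v, cluster)| / (density * |cluster|)` is at
#' least `cp_min`. A terminated cluster of at least `min_size` nodes is
#' emitted, the graph is updated, weights are recomputed and the process
#' repeats until no further cluster forms.
#'
#' Two update modes are provided. The default, `"overlapping"`, removes
#' only the emitted cluster's internal edges so its members stay available
#' to later clusters (overlap is possible and the edge count strictly
#' decreases, guaranteeing termination). `"partition"` removes the member
#' nodes outright, yielding disjoint clusters.
#'
#' @inheritParams mcode
#' @param d_min minimum cluster density (default 0.9).
#' @param cp_min minimum cluster property of an admitted node
#'   (default 0.5).
#' @param min_size minimum emitted cluster size (default 2).
#' @param mode graph-update mode, `"overlapping"` (default) or
#'   `"partition"`.
#' @return a [clustering()] with algorithm tag `"dpclus"`.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' dpclus(g)
#' @export
dpclus <- function(graph, d_min = 0.9, cp_min = 0.5, min_size = 2,
                   mode = c("overlapping", "partition")) {
  mode <- match.arg(mode)
  stopifnot(d_min >= 0, d_min <= 1, cp_min >= 0, min_size >= 1)
  params <- list(d_min = d_min, cp_min = cp_min, min_size = min_size,
                 mode = mode)
  A <- adj_matrix_from_graph(graph)
  if (nrow(A) == 0L) {
    return(clustering(list(), algorithm = "dpclus", params = params))
  }

  out <- list()
  repeat {
    if (sum(A) == 0) break
    nodes <- rownames(A)
    nw <- cn_node_weights(A)
    deg <- rowSums(A)
    seeds <- order_by_weight(nodes[deg > 0], nw, deg)
    emitted <- FALSE
    for (seed in seeds) {
      members <- dpclus_grow(A, nw, seed, d_min, cp_min)
      if (length(members) >= min_size) {
        out[[length(out) + 1L]] <- members
        if (mode == "overlapping") {
          A[members, members] <- 0
        } else {
          keep <- setdiff(nodes, members)
          A <- A[keep, keep, drop = FALSE]
        }
        emitted <- TRUE
        break
      }
    }
    if (!emitted) break
  }
  clustering(out, algorithm = "dpclus", params = params)
}

# greedy growth of one DPClus cluster from `seed` on adjacency matrix A
dpclus_grow <- function(A, nw, seed, d_min, cp_min) {
  nodes <- rownames(A)
  members <- seed
  e_in <- 0
  repeat {
    k_into <- colSums(A[members, , drop = FALSE])
    k_into[members] <- 0
    cand <- nodes[k_into > 0]
    if (length(cand) == 0L) break
    cand <- cand[order(-k_into[cand], -nw[cand], cand, method = "radix")]
    n_cur <- length(members)
    dens_cur <- if (n_cur <= 1L) 1.0 else 2 * e_in / (n_cur * (n_cur - 1))
    added <- FALSE
    for (v in cand) {
      e_new <- e_in + k_into[v]
      dens_new <- 2 * e_new / ((n_cur + 1) * n_cur)
      cp <- k_into[v] / (dens_cur * n_cur)
      if (dens_new >= d_min && cp >= cp_min) {
        members <- c(members, v)
        e_in <- e_new
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  members
}
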