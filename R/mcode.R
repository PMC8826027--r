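#' MCODE: molecular complex detection
#'
#' Agglomerative detection of dense regions in a PPI graph. Each vertex is
#' weighted by its local neighbourhood density: the highest k-core of the
#' subgraph induced on the closed neighbourhood of `v` is found, and
#' `weight(v) = k * density(core)` where
#' `density = 2|E| / (|V|(|V|-1))`. Clusters are grown breadth-first from
#' the highest-weight unused vertex, admitting neighbours whose weight is
#' at least `(1 - vwp)` times the seed weight; a vertex can join at most
#' one grown cluster. Optional post-processing: *haircut* iteratively
#' strips members with fewer than two within-cluster edges, and *fluff*
#' adds outside neighbours whose closed-neighbourhood density exceeds
#' `fluff_density` (fluffed vertices may belong to several clusters).
#' Clusters below `min_size` are discarded. Output is deterministic,
#' ordered by seed weight (descending), with all ties broken by weight,
#' then degree, then identifier.
#'
#' @param graph an undirected [igraph::igraph] with named vertices
#'   (typically a study graph from [induce_study_graph()]).
#' @param vwp vertex weight percentage in `[0,1]`; growth threshold is
#'   `(1 - vwp) * seed_weight`. Default 0.2.
#' @param haircut logical; strip weakly attached members (default `TRUE`).
#' @param fluff logical; expand clusters with densely connected
#'   neighbours (default `FALSE`).
#' @param fluff_density closed-neighbourhood density threshold for fluff
#'   (default 0.2).
#' @param min_size minimum emitted cluster size (default 3).
#' @return a [clustering()] with algorithm tag `"mcode"`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' mcode(g)
#' @export
mcode <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                  fluff_density = 0.2, min_size = 3) {
  stopifnot(vwp >= 0, vwp <= 1, fluff_density >= 0, fluff_density <= 1,
            min_size >= 1)
  params <- list(vwp = vwp, haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density, min_size = min_size)
  adj <- adj_from_graph(graph)
  nodes <- names(adj)
  if (length(nodes) == 0L) {
    return(clustering(list(), algorithm = "mcode", params = params))
  }

  weight <- stats::setNames(
    vapply(nodes, function(v) mcode_vertex_weight(adj, v), numeric(1)),
    nodes)
  degree <- vapply(adj, length, integer(1))

  used <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  order_seeds <- order_by_weight(nodes, weight, degree)
  raw <- list()
  seed_w <- numeric(0)

  for (seed in order_seeds) {
    if (used[seed]) next
    threshold <- (1 - vwp) * weight[seed]
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0L) {
      cand <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                      members)
      cand <- cand[!used[cand] & weight[cand] >= threshold]
      cand <- order_by_weight(cand, weight, degree)
      if (length(cand) == 0L) break
      used[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    raw[[length(raw) + 1L]] <- members
    seed_w <- c(seed_w, weight[seed])
  }

  out <- list()
  for (members in raw) {
    if (haircut) members <- mcode_haircut(adj, members)
    if (fluff && length(members) > 0L) {
      nb <- neighbours_of_set(adj, members)
      keep <- vapply(nb, function(u) {
        subgraph_density(adj, c(u, adj[[u]])) > fluff_density
      }, logical(1))
      members <- sort(c(members, nb[keep]))
    }
    out[[length(out) + 1L]] <- members
  }
  keep <- lengths(out) >= min_size
  clustering(out[keep], algorithm = "mcode", params = params)
}

# weight(v) = k * density of the highest k-core of the closed
# neighbourhood of v
mcode_vertex_weight <- function(adj, v) {
  nbh <- c(v, adj[[v]])
  if (length(nbh) < 2L) return(0)
  core <- highest_k_core(adj, nbh)
  if (core$k == 0L) return(0)
  core$k * subgraph_density(adj, core$members)
}

# highest k-core of the subgraph induced on `nodes`, by iterative peeling
highest_k_core <- function(adj, nodes) {
  best <- list(k = 0L, members = nodes)
  current <- nodes
  k <- 1L
  repeat {
    # peel vertices of induced degree < k until stable
    repeat {
      if (length(current) == 0L) return(best)
      deg <- vapply(current, function(u) sum(adj[[u]] %in% current),
                    integer(1))
      drop <- deg < k
      if (!any(drop)) break
      current <- current[!drop]
    }
    best <- list(k = k, members = current)
    k <- k + 1L
  }
}

# iteratively remove members with fewer than two within-cluster edges
mcode_haircut <- function(adj, members) {
  repeat {
    if (length(members) == 0L) return(members)
    deg <- vapply(members, function(u) sum(adj[[u]] %in% members),
                  integer(1))
    drop <- deg < 2L
    if (!any(drop)) return(sort(members))
    members <- members[!drop]
  }
}
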