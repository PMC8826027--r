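#' COACH: core-attachment complex discovery
#'
#' Discovers complexes with an explicit core-attachment structure. For
#' every vertex `v` a preliminary core is formed from `v` plus those
#' neighbours whose degree within the subgraph induced on the closed
#' neighbourhood of `v` is at least the average degree of that subgraph.
#' Cores whose induced density falls below `core_density` are discarded.
#' Redundant cores are removed with the neighbourhood-affinity criterion
#' `NA(A,B) = |A n B|^2 / (|A||B|) >= affinity_threshold`, keeping the
#' denser core, then the larger, then the lexicographically first. Every
#' outside vertex adjacent to more than half of a core's members is
#' attached to it; the final complex is the core plus its attachments,
#' emitted when it reaches `min_size`. Complexes overlap by construction.
#'
#' @inheritParams mcode
#' @param core_density minimum density of a preliminary core
#'   (default 0.7).
#' @param affinity_threshold neighbourhood-affinity threshold above which
#'   two cores are considered redundant (default 0.225).
#' @param min_size minimum emitted complex size (default 3).
#' @return a [clustering()] with algorithm tag `"coach"`.
#' @examples
#' g <- igraph::make_full_graph(6)
#' igraph::V(g)$name <- letters[1:6]
#' coach(g)
#' @export
coach <- function(graph, core_density = 0.7, affinity_threshold = 0.225,
                  min_size = 3) {
  stopifnot(core_density >= 0, core_density <= 1,
            affinity_threshold >= 0, affinity_threshold <= 1,
            min_size >= 1)
  params <- list(core_density = core_density,
                 affinity_threshold = affinity_threshold,
                 min_size = min_size)
  adj <- adj_from_graph(graph)
  nodes <- names(adj)
  if (length(nodes) == 0L) {
    return(clustering(list(), algorithm = "coach", params = params))
  }

  # preliminary cores, one per vertex with a non-empty neighbourhood
  cores <- list()
  for (v in nodes) {
    if (length(adj[[v]]) == 0L) next
    nbh <- c(v, adj[[v]])
    deg_in <- vapply(nbh, function(u) sum(adj[[u]] %in% nbh), integer(1))
    avg <- mean(deg_in)
    core <- sort(c(v, adj[[v]][deg_in[adj[[v]]] >= avg]))
    if (subgraph_density(adj, core) < core_density) next
    cores[[length(cores) + 1L]] <- core
  }
  if (length(cores) == 0L) {
    return(clustering(list(), algorithm = "coach", params = params))
  }
  cores <- unique(cores)

  # redundancy removal: keep denser, then larger, then lexicographically
  # first among affine (NA >= threshold) cores
  dens <- vapply(cores, function(co) subgraph_density(adj, co), numeric(1))
  size <- lengths(cores)
  lex <- vapply(cores, paste, character(1), collapse = "\t")
  ord <- order(-dens, -size, lex, method = "radix")
  kept <- list()
  for (i in ord) {
    redundant <- any(vapply(kept, function(k) {
      neighbourhood_affinity(cores[[i]], k) >= affinity_threshold
    }, logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- cores[[i]]
  }

  # attach outside vertices adjacent to more than half of a core
  out <- list()
  for (core in kept) {
    outside <- setdiff(nodes, core)
    att <- outside[vapply(outside, function(u) {
      sum(adj[[u]] %in% core) > 0.5 * length(core)
    }, logical(1))]
    complex <- sort(c(core, att))
    if (length(complex) >= min_size) {
      out[[length(out) + 1L]] <- complex
    }
  }
  out <- unique(out)
  clustering(out, algorithm = "coach", params = params)
}
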