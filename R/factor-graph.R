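#' Build the bipartite gene-complex factor graph
#'
#' Turns a clustering into the bipartite membership structure that defines
#' the sparsity mask of the predictive model: one complex node per
#' cluster, one membership edge per (member gene, cluster) pair. Genes
#' that belong to no cluster keep their position in `gene_index` but have
#' no edges, which is the feature-selection effect of the clustering
#' step.
#'
#' @param clustering a non-empty [clustering()] whose members are all in
#'   `gene_index`.
#' @param gene_index ordered character vector of all measured gene names
#'   (the model's input order).
#' @return an object of class `factor_graph` with elements `gene_index`,
#'   `complex_names`, `memberships` (two-column character matrix
#'   `gene`, `complex`) and `origin = "clustered"`.
#' @examples
#' cl <- clustering(list(c1 = c("g1", "g2"), c2 = c("g2", "g3")))
#' fg <- build_factor_graph(cl, paste0("g", 1:4))
#' count_edges(fg) # 4
#' @export
build_factor_graph <- function(clustering, gene_index) {
  stopifnot(inherits(clustering, "clustering"))
  gene_index <- as.character(gene_index)
  if (anyDuplicated(gene_index)) stop("duplicate names in gene_index")
  if (length(clustering$clusters) == 0L) {
    stop("empty clustering: no factor graph (and no model) can be built")
  }
  missing <- setdiff(unique(unlist(clustering$clusters, use.names = FALSE)),
                     gene_index)
  if (length(missing) > 0L) {
    stop("cluster member(s) absent from gene_index: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  genes <- unlist(clustering$clusters, use.names = FALSE)
  cx <- rep(names(clustering$clusters), lengths(clustering$clusters))
  new_factor_graph(gene_index, names(clustering$clusters),
                   cbind(gene = genes, complex = cx), origin = "clustered")
}

new_factor_graph <- function(gene_index, complex_names, memberships,
                             origin) {
  memberships <- matrix(as.character(memberships), ncol = 2,
                        dimnames = list(NULL, c("gene", "complex")))
  if (anyDuplicated(paste0(memberships[, 1], "\r", memberships[, 2]))) {
    stop("duplicate membership pairs")
  }
  structure(list(gene_index = as.character(gene_index),
                 complex_names = as.character(complex_names),
                 memberships = memberships,
                 origin = origin),
            class = "factor_graph")
}

#' @export
print.factor_graph <- function(x, ...) {
  cat("factor_graph (", x$origin, "): ", length(x$gene_index), " genes, ",
      length(x$complex_names), " complexes, ", nrow(x$memberships),
      " membership edges\n", sep = "")
  invisible(x)
}

#' Number of membership edges (first-layer parameters)
#'
#' For a clustered factor graph this equals the sum of the cluster sizes
#' and is the first-layer parameter count of the masked model (bias terms
#' are not counted).
#'
#' @param fg a `factor_graph`.
#' @return integer edge count.
#' @export
count_edges <- function(fg) {
  stopifnot(inherits(fg, "factor_graph"))
  nrow(fg$memberships)
}

#' Edge count of the fully connected counterpart
#'
#' A fully connected two-layer model with `k` inputs and `l` hidden units
#' has `k * l` first-layer weights (biases excluded); this is the
#' reference against which the sparsity of a clustered factor graph is
#' measured.
#'
#' @param k number of input genes (non-negative integer).
#' @param l number of hidden units / complexes (non-negative integer).
#' @return `k * l` as a double (counts can exceed integer range).
#' @examples
#' fc_edge_count(24368, 40) # 974720
#' @export
fc_edge_count <- function(k, l) {
  if (k < 0 || l < 0) stop("k and l must be non-negative")
  as.numeric(k) * as.numeric(l)
}

#' Random factor graph with random dimensions (control model R)
#'
#' Control structure for testing whether a discovered factor graph
#' carries information beyond mere sparsity. The number of pseudo
#' complexes `l` is drawn uniformly from `l_range` (default `[30, 6000]`,
#' inclusive), the number of membership edges `u` uniformly from
#' `[1, l * k]`, and the `u` edges are placed uniformly at random without
#' replacement over the `l * k` bipartite grid.
#'
#' @param k number of input genes; `gene_index` overrides it when given.
#' @param gene_index optional gene names (defaults to `g1..gk`).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param l_range inclusive integer range for the number of complexes.
#' @return a `factor_graph` with origin `"random_R"`.
#' @export
random_factor_graph <- function(k, gene_index = NULL, seed = 1L,
                                l_range = c(30L, 6000L)) {
  if (is.null(gene_index)) gene_index <- paste0("g", seq_len(k))
  gene_index <- as.character(gene_index)
  k <- length(gene_index)
  stopifnot(k >= 1L, l_range[1] >= 1L, l_range[2] >= l_range[1])
  withr_seed(seed, {
    l <- sample(seq.int(l_range[1], l_range[2]), 1L)
    u <- sample.int(as.numeric(l) * k, 1L)
    place_random_memberships(gene_index, l, u, origin = "random_R")
  })
}

#' Random factor graph matched to a template (control model M)
#'
#' Keeps the template's number of complexes `l` and number of membership
#' edges `u` but re-draws the edges uniformly at random without
#' replacement, destroying the biological structure while conserving the
#' parameter budget. Complexes that receive no edges are permitted (their
#' model activity is constant).
#'
#' @param template a `factor_graph` supplying `l`, `u` and the gene
#'   index.
#' @param seed integer seed.
#' @return a `factor_graph` with origin `"random_M"` and exactly the
#'   template's `l` and `u`.
#' @export
random_factor_graph_matched <- function(template, seed = 1L) {
  stopifnot(inherits(template, "factor_graph"))
  l <- length(template$complex_names)
  u <- nrow(template$memberships)
  k <- length(template$gene_index)
  if (l < 1L || u < 1L) stop("template must have l >= 1 and u >= 1")
  if (as.numeric(u) > as.numeric(l) * k) {
    stop("impossible configuration: u > l * k")
  }
  withr_seed(seed, {
    place_random_memberships(template$gene_index, l, u,
                             origin = "random_M")
  })
}

# place u distinct (gene, complex) pairs uniformly over the l*k grid
place_random_memberships <- function(gene_index, l, u, origin) {
  k <- length(gene_index)
  idx <- sample.int(as.numeric(l) * k, u)  # without replacement
  gene_i <- ((idx - 1L) %% k) + 1L
  complex_i <- ((idx - 1L) %/% k) + 1L
  complex_names <- paste0("rc_", seq_len(l))
  new_factor_graph(gene_index, complex_names,
                   cbind(gene = gene_index[gene_i],
                         complex = complex_names[complex_i]),
                   origin = origin)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Write / read a factor graph as tab-separated text
#'
#' The file starts with header comment lines recording `k`, `l`, `u` and
#' the origin, then a `gene <tab> complex` pair per line. Genes with no
#' membership are recorded in a trailing `#genes` line so the full gene
#' index round-trips.
#'
#' @param fg a `factor_graph`.
#' @param path file path.
#' @return `write_factor_graph` returns `path` invisibly;
#'   `read_factor_graph` returns a `factor_graph`.
#' @export
write_factor_graph <- function(fg, path) {
  stopifnot(inherits(fg, "factor_graph"))
  header <- c(
    paste0("#k\t", length(fg$gene_index)),
    paste0("#l\t", length(fg$complex_names)),
    paste0("#u\t", nrow(fg$memberships)),
    paste0("#origin\t", fg$origin),
    paste0("#genes\t", paste(fg$gene_index, collapse = "\t")),
    paste0("#complexes\t", paste(fg$complex_names, collapse = "\t")))
  body <- paste(fg$memberships[, "gene"], fg$memberships[, "complex"],
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_factor_graph
#' @export
read_factor_graph <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key) {
    row <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (length(row) == 0L) stop("missing header line #", key)
    strsplit(row[[1]], "\t", fixed = TRUE)[[1]][-1L]
  }
  gene_index <- get_meta("genes")
  complex_names <- get_meta("complexes")
  origin <- get_meta("origin")
  pairs <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  if (is.null(pairs)) stop("factor graph file has no membership edges")
  new_factor_graph(gene_index, complex_names,
                   cbind(gene = pairs[, 1], complex = pairs[, 2]),
                   origin = origin)
}
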