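#' Read a protein-protein interaction network from a delimited edge list
#'
#' Reads an edge list in the STRING protein-links dialect: one interaction
#' per row with two identifier columns and an optional third numeric
#' confidence score. Space- and tab-delimited files are both accepted, and
#' a header row is auto-detected (a non-numeric third field, or the
#' literal column names STRING uses). The result is an undirected simple
#' graph: duplicate rows, reversed duplicates and self-loops are removed.
#'
#' @param path path to the edge-list file.
#' @param min_score optional numeric threshold; rows whose third-column
#'   score is below it are dropped. Default `NULL` keeps all edges (no
#'   confidence cut-off is applied unless requested).
#' @param delimiter field separator; `""` (default) splits on any
#'   whitespace, which covers both space- and tab-delimited files.
#' @param id_map optional two-column data frame (or path to a two-column
#'   delimited file) mapping node identifiers to a new namespace, e.g.
#'   Ensembl protein ids to gene symbols. Applied before de-duplication;
#'   unmapped identifiers are kept as-is.
#' @return an [igraph::igraph] undirected simple graph with character
#'   vertex names and a graph attribute `n_self_loops_dropped`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B 900", "B C 100", "A A 500"), f)
#' g <- read_ppi_edgelist(f, min_score = 400)
#' igraph::ecount(g) # 1
#' @export
read_ppi_edgelist <- function(path, min_score = NULL, delimiter = "",
                              id_map = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)

  split_row <- function(x) {
    if (identical(delimiter, "")) strsplit(trimws(x), "[ \t]+")[[1]]
    else strsplit(x, delimiter, fixed = TRUE)[[1]]
  }
  first <- split_row(lines[[1]])
  has_header <- (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3]))) ) ||
    any(tolower(first) %in% c("protein1", "protein2", "combined_score", "node1", "node2"))
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L) stop("edge-list file has a header but no data rows: ", path)

  rows <- lapply(lines, split_row)
  ncols <- lengths(rows)
  bad <- which(ncols < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list row (fewer than 2 columns) at line ",
         bad[1L] + has_header, " of ", path)
  }
  a <- vapply(rows, `[[`, character(1), 1L)
  b <- vapply(rows, `[[`, character(1), 2L)

  if (!is.null(min_score)) {
    if (any(ncols < 3L)) {
      stop("min_score given but some rows lack a third score column")
    }
    score <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
    if (anyNA(score)) {
      stop("non-numeric score at line ",
           which(is.na(score))[1L] + has_header, " of ", path)
    }
    keep <- score >= min_score
    a <- a[keep]; b <- b[keep]
  }

  if (!is.null(id_map)) {
    if (is.character(id_map) && length(id_map) == 1L) {
      id_map <- utils::read.table(id_map, header = FALSE,
                                  stringsAsFactors = FALSE,
                                  colClasses = "character")
    }
    stopifnot(ncol(id_map) >= 2L)
    map <- stats::setNames(as.character(id_map[[2L]]),
                           as.character(id_map[[1L]]))
    remap <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
    a <- remap(a); b <- remap(b)
  }

  self <- a == b
  n_self <- sum(self)
  if (n_self > 0L) {
    message(n_self, " self-loop row(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste0(lo, "\r", hi))
  g <- igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]), directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_self_loops_dropped", n_self)
  g
}

#' Construct an expression dataset
#'
#' Container for an m x k expression matrix with ordered gene names,
#' sample identifiers and optional categorical phenotype labels.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param gene_names character vector of k unique gene names.
#' @param sample_ids character vector of m unique sample identifiers.
#' @param labels optional factor (or vector coerced to factor) of length m.
#' @return an object of class `expression_dataset` with elements
#'   `values`, `gene_names`, `sample_ids`, `labels`.
#' @export
expression_dataset <- function(values, gene_names = colnames(values),
                               sample_ids = rownames(values),
                               labels = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  sample_ids <- as.character(sample_ids)
  if (ncol(values) != length(gene_names)) {
    stop("column count (", ncol(values), ") != number of gene names (",
         length(gene_names), ")")
  }
  if (anyDuplicated(gene_names)) {
    stop("duplicate gene names: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.null(labels)) {
    if (length(labels) != nrow(values)) {
      stop("labels length (", length(labels), ") != number of samples (",
           nrow(values), ")")
    }
    labels <- as.factor(labels)
  }
  dimnames(values) <- list(sample_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "samples x",
      ncol(x$values), "genes\n")
  if (!is.null(x$labels)) {
    cat("labels:", paste(levels(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects samples as rows and genes as columns, with a header row of gene
#' names. An optional first column of sample identifiers is auto-detected
#' (non-numeric first data field under an empty or `"sample"`-like first
#' header field), and an optional label column can be pulled out of the
#' table by name.
#'
#' @param path path to a CSV/TSV file.
#' @param label_column optional name of a column holding phenotype labels.
#' @param sep field separator (default `,`).
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, label_column = NULL, sep = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  cn <- colnames(df)
  sample_ids <- NULL
  if (tolower(cn[1L]) %in% c("", "sample", "sample_id", "id", "x") ||
      is.na(suppressWarnings(as.numeric(df[1L, 1L])))) {
    sample_ids <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    cn <- colnames(df)
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% cn) {
      stop("unknown label column: ", label_column)
    }
    labels <- df[[label_column]]
    df <- df[, cn != label_column, drop = FALSE]
    cn <- colnames(df)
  }
  if (anyDuplicated(cn)) {
    stop("duplicate gene names in header: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at row ", idx[1L],
         ", column '", cn[idx[2L]], "'")
  }
  expression_dataset(num, gene_names = cn, sample_ids = sample_ids,
                     labels = labels)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression_matrix()]: writes a header of gene names, a
#' leading `sample` column and, when present, a trailing `label` column.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @param sep field separator (default `,`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(sample = dataset$sample_ids,
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$labels)) df$label <- as.character(dataset$labels)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Induce the study subgraph on the genes measured in a dataset
#'
#' The study graph is the subgraph of the PPI network induced on the
#' intersection of the network's nodes with the measured gene set: its
#' nodes are the common identifiers and its edges are exactly the network
#' edges with both endpoints in that set. Genes absent from the network
#' (and network nodes absent from the gene set) are dropped and counted in
#' the returned provenance attributes.
#'
#' @param ppi an undirected [igraph::igraph] with named vertices.
#' @param genes character vector of measured gene identifiers.
#' @return the induced subgraph, with graph attributes
#'   `n_genes_dropped` (measured genes not in the network) and
#'   `n_ppi_dropped` (network nodes not measured).
#' @export
induce_study_graph <- function(ppi, genes) {
  stopifnot(igraph::is_igraph(ppi))
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set")
  vs <- intersect(igraph::V(ppi)$name, genes)
  if (length(vs) == 0L) {
    stop("no overlap between the gene set and the network nodes; ",
         "check that both use the same identifier namespace ",
         "(an id_map can be supplied to read_ppi_edgelist)")
  }
  g <- igraph::induced_subgraph(ppi, vs)
  g <- igraph::set_graph_attr(g, "n_genes_dropped", length(setdiff(genes, vs)))
  g <- igraph::set_graph_attr(g, "n_ppi_dropped",
                              igraph::vcount(ppi) - length(vs))
  g
}

#' Write / read a clustering as tab-separated text
#'
#' One cluster per line: the cluster name, a tab, then the tab-separated
#' member identifiers. `read_clusters` is the exact inverse of
#' `write_clusters`.
#'
#' @param clustering a [clustering()] object.
#' @param path file path.
#' @return `write_clusters` returns `path` invisibly; `read_clusters`
#'   returns a [clustering()].
#' @export
write_clusters <- function(clustering, path) {
  stopifnot(inherits(clustering, "clustering"))
  lines <- vapply(seq_along(clustering$clusters), function(i) {
    paste(c(names(clustering$clusters)[i], clustering$clusters[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clusters
#' @param algorithm algorithm tag recorded on the clustering read back in.
#' @export
read_clusters <- function(path, algorithm = "file") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(clustering(list(), algorithm = algorithm))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate cluster names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  members <- lapply(parts, function(p) p[-1L])
  if (any(lengths(members) == 0L)) {
    stop("cluster with empty member list at line ",
         which(lengths(members) == 0L)[1L])
  }
  clustering(stats::setNames(members, nms), algorithm = algorithm)
}
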