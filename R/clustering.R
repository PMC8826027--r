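#' Clustering container
#'
#' An ordered list of named, possibly overlapping gene sets, as produced
#' by the complex-discovery algorithms. Members are stored as sorted
#' character vectors; cluster order is meaningful (emission order).
#'
#' @param clusters named list of character vectors (cluster members).
#'   Unnamed lists are named `<algorithm>_<index>`.
#' @param algorithm tag identifying the producing algorithm.
#' @param params named list of the parameters used.
#' @return an object of class `clustering` with elements `clusters`,
#'   `algorithm`, `params`.
#' @export
clustering <- function(clusters, algorithm = "unknown", params = list()) {
  stopifnot(is.list(clusters))
  clusters <- lapply(clusters, function(m) sort(unique(as.character(m))))
  if (length(clusters) > 0L) {
    if (is.null(names(clusters)) || any(!nzchar(names(clusters)))) {
      names(clusters) <- paste0(algorithm, "_", seq_along(clusters))
    }
    if (anyDuplicated(names(clusters))) stop("duplicate cluster names")
  }
  structure(list(clusters = clusters, algorithm = algorithm,
                 params = params),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("clustering (", x$algorithm, "): ", length(x$clusters),
      " clusters\n", sep = "")
  if (length(x$clusters) > 0L) {
    s <- lengths(x$clusters)
    cat("sizes: min", min(s), "median", stats::median(s), "max", max(s), "\n")
  }
  invisible(x)
}

#' @export
length.clustering <- function(x) length(x$clusters)

#' Descriptive statistics of a clustering
#'
#' Reports the number of clusters and the maximum, minimum and arithmetic
#' mean cluster size, the summary conventionally tabulated for
#' protein-complex predictions. An empty clustering reports zeros.
#'
#' @param clustering a [clustering()].
#' @param digits decimal places for the mean (default 2).
#' @return a list with `n_clusters`, `max_size`, `min_size`, `mean_size`.
#' @examples
#' cl <- clustering(list(a = c("x", "y", "z"), b = letters[1:5]))
#' cluster_stats(cl)
#' @export
cluster_stats <- function(clustering, digits = 2) {
  stopifnot(inherits(clustering, "clustering"))
  if (length(clustering$clusters) == 0L) {
    return(list(n_clusters = 0L, max_size = 0L, min_size = 0L,
                mean_size = 0))
  }
  s <- lengths(clustering$clusters)
  list(n_clusters = length(s), max_size = max(s), min_size = min(s),
       mean_size = round(mean(s), digits))
}

# neighbourhood affinity NA(A,B) = |A n B|^2 / (|A| |B|)
neighbourhood_affinity <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Match a predicted clustering against a reference
#'
#' Scores complex recovery with the neighbourhood-affinity criterion: a
#' predicted cluster A matches a reference cluster B when
#' \eqn{NA(A,B) = |A \cap B|^2 / (|A||B|) \ge \omega}. Returns the
#' fraction of predicted clusters matched by some reference cluster
#' (precision-like), the fraction of reference clusters matched by some
#' predicted cluster (recall-like), and their harmonic mean.
#'
#' @param predicted,reference [clustering()] objects; `reference` must be
#'   non-empty.
#' @param omega affinity threshold in (0, 1].
#' @return list with `precision`, `recall`, `f_measure`.
#' @export
match_score <- function(predicted, reference, omega = 0.25) {
  stopifnot(inherits(predicted, "clustering"),
            inherits(reference, "clustering"),
            omega > 0, omega <= 1)
  if (length(reference$clusters) == 0L) stop("empty reference clustering")
  if (length(predicted$clusters) == 0L) {
    return(list(precision = 0, recall = 0, f_measure = 0))
  }
  na_mat <- outer(predicted$clusters, reference$clusters,
                  Vectorize(function(a, b) neighbourhood_affinity(a, b)))
  precision <- mean(apply(na_mat, 1L, max) >= omega)
  recall <- mean(apply(na_mat, 2L, max) >= omega)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f)
}
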