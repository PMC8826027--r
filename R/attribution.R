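#' Layer integrated gradients for complex nodes
#'
#' Attributes a trained model's class score to the hidden complex
#' activities with integrated gradients evaluated at the complex layer.
#' Along the straight path `x(alpha) = baseline + alpha (x - baseline)`,
#' `alpha in {1/S, ..., 1}`, the attribution of complex `i` is
#' \deqn{\sum_s [h_i(x(\alpha_s)) - h_i(x(\alpha_{s-1}))] \;
#'       \partial \mathrm{logit}_t / \partial h_i |_{x(\alpha_s)}}
#' Because the complex-to-class map of this model is affine, the gradient
#' term is the constant output weight and the sum telescopes, so the
#' completeness identity
#' `sum_i attribution_i = logit_t(x) - logit_t(baseline)` holds exactly
#' for any number of steps.
#'
#' @param model a trained `sparse_model`.
#' @param X numeric m x k matrix of inputs to attribute (columns in the
#'   model's gene order).
#' @param target_class class to attribute, as a label from the model's
#'   vocabulary or a column index.
#' @param baseline numeric length-k baseline input, or `"zeros"`
#'   (default) / `"mean"` (column means of `X`).
#' @param steps number of path steps (default 128).
#' @return an object of class `attribution_report`: `attributions`
#'   (m x l matrix), `importance` (named per-complex mean absolute
#'   attribution), `ranking` (complex names by descending importance,
#'   ties by name), `steps`, `baseline`, `target_class`.
#' @export
layer_integrated_gradients <- function(model, X, target_class,
                                       baseline = "zeros", steps = 128L) {
  stopifnot(inherits(model, "sparse_model"), steps >= 1)
  X <- as.matrix(X)
  k <- nrow(model$W1)
  if (ncol(X) != k) stop("X has ", ncol(X), " columns; expected ", k)

  if (is.character(target_class)) {
    if (is.null(model$class_levels) ||
        !target_class %in% model$class_levels) {
      stop("unknown target class: ", target_class)
    }
    t_idx <- match(target_class, model$class_levels)
  } else {
    t_idx <- as.integer(target_class)
    if (t_idx < 1L || t_idx > model$n_classes) {
      stop("target class index out of range")
    }
  }

  baseline_desc <- "custom"
  if (identical(baseline, "zeros")) {
    baseline <- numeric(k); baseline_desc <- "zeros"
  } else if (identical(baseline, "mean")) {
    baseline <- colMeans(X); baseline_desc <- "column means"
  }
  stopifnot(length(baseline) == k)

  # gradient of the target logit w.r.t. the complex activities: the
  # output layer is affine, so it is the constant column of W2
  grad_h <- model$W2[, t_idx]

  m <- nrow(X)
  l <- ncol(model$W1)
  base_mat <- matrix(baseline, m, k, byrow = TRUE)
  h_prev <- model_forward(model, base_mat)$activities
  attributions <- matrix(0, m, l,
                         dimnames = list(rownames(X),
                                         model$fg$complex_names))
  for (s in seq_len(steps)) {
    alpha <- s / steps
    Xa <- base_mat + alpha * (X - base_mat)
    h_s <- model_forward(model, Xa)$activities
    if (any(!is.finite(h_s))) stop("non-finite activities on the path")
    attributions <- attributions +
      sweep(h_s - h_prev, 2L, grad_h, `*`)
    h_prev <- h_s
  }

  importance <- colMeans(abs(attributions))
  ranking <- names(importance)[order(-importance, names(importance),
                                     method = "radix")]
  structure(list(attributions = attributions, importance = importance,
                 ranking = ranking, steps = as.integer(steps),
                 baseline = baseline_desc,
                 target_class = if (!is.null(model$class_levels))
                   model$class_levels[t_idx] else t_idx),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("attribution_report: target class '", x$target_class, "', ",
      ncol(x$attributions), " complexes, ", nrow(x$attributions),
      " samples, ", x$steps, " steps, baseline ", x$baseline, "\n",
      sep = "")
  cat("top complexes:", paste(utils::head(x$ranking, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank complexes by attributed importance
#'
#' Orders complexes by descending mean absolute attribution (ties broken
#' by name).
#'
#' @param report an `attribution_report`.
#' @return character vector of complex names, most important first.
#' @export
rank_complexes <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  report$ranking
}

#' Export top-ranked complexes as a GMT gene-set file
#'
#' Writes the members of the `top_n` highest-ranked complexes in the
#' standard Gene Matrix Transposed format: one set per line with name,
#' description (rank and importance) and tab-separated members, in ranked
#' order. The file can be fed to external enrichment tools.
#'
#' @param clustering the [clustering()] the model was built from.
#' @param report an `attribution_report` ranking its complexes.
#' @param top_n number of top complexes to export (`<=` number of
#'   complexes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_gmt <- function(clustering, report, top_n, path) {
  stopifnot(inherits(clustering, "clustering"),
            inherits(report, "attribution_report"),
            top_n <= length(report$ranking))
  top <- utils::head(report$ranking, top_n)
  lines <- vapply(seq_along(top), function(i) {
    nm <- top[i]
    members <- clustering$clusters[[nm]]
    if (is.null(members)) stop("complex '", nm, "' not in clustering")
    desc <- sprintf("rank=%d;importance=%.6g", i, report$importance[nm])
    paste(c(nm, desc, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
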