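#' Repeated class-stratified train/test splits
#'
#' Builds `n_repeats` independent stratified splits with a `test_fraction`
#' hold-out (80:20 by default). Within every repeat each class contributes
#' `round(test_fraction * n_class)` samples to the test set, so the test
#' class proportions are within one sample of the stratified ideal. One
#' master seed derives a per-repeat seed, recorded in the plan.
#'
#' @param labels factor (or vector) of per-sample class labels; every
#'   class needs at least 2 samples.
#' @param n_repeats number of repeated splits (default 5).
#' @param test_fraction hold-out fraction (default 0.2).
#' @param seed master integer seed.
#' @return an object of class `split_plan`: list with `splits` (each a
#'   list of `train`/`test` integer indices and the repeat seed),
#'   `n_repeats`, `test_fraction`, `seed`.
#' @export
make_splits <- function(labels, n_repeats = 5L, test_fraction = 0.2,
                        seed = 1L) {
  labels <- as.factor(labels)
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  m <- length(labels)
  splits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    r_seed <- as.integer((as.numeric(seed) * 1000 + r) %% .Machine$integer.max)
    test_idx <- withr_seed(r_seed, {
      idx <- integer(0)
      for (cl in levels(labels)) {
        members <- which(labels == cl)
        n_test <- round(test_fraction * length(members))
        n_test <- max(1L, min(n_test, length(members) - 1L))
        idx <- c(idx, sample(members, n_test))
      }
      sort(idx)
    })
    splits[[r]] <- list(train = setdiff(seq_len(m), test_idx),
                        test = test_idx, seed = r_seed)
  }
  structure(list(splits = splits, n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Balanced classification accuracy (percent)
#'
#' The unweighted mean of per-class recall, expressed as a percentage.
#' Only classes represented in `y_true` enter the mean; a constant
#' classifier therefore scores exactly `100 / C` on data with `C`
#' represented classes.
#'
#' @param y_true,y_pred vectors of true and predicted class labels.
#' @return balanced accuracy in `[0, 100]`.
#' @examples
#' balanced_accuracy(c("a", "a", "b", "b"), c("a", "a", "a", "a")) # 50
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  classes <- sort(unique(y_true))
  if (length(classes) == 0L) stop("no true classes present")
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  100 * mean(recalls)
}

# Mann-Whitney AUC for a binary split; ties count one half
binary_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Prevalence-weighted one-vs-rest ROC AUC
#'
#' Computes a one-vs-rest ROC AUC for every class and averages them with
#' weights equal to the empirical class prevalence in `y_true`. Ties in
#' the scores count one half (the Mann-Whitney convention). A class
#' without both positives and negatives is skipped with a warning and the
#' remaining weights are renormalized. The binary case uses the same
#' two-class weighted average, not the single-class convention.
#'
#' @param y_true vector of true class labels.
#' @param scores numeric m x n_classes matrix of class scores; column
#'   names, when present, name the classes (otherwise columns follow the
#'   sorted unique labels).
#' @return the weighted AUC in `[0, 1]`.
#' @export
weighted_ovr_auc <- function(y_true, scores) {
  y_true <- as.character(y_true)
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y_true)) {
    stop("scores rows != length(y_true)")
  }
  if (any(!is.finite(scores))) stop("non-finite scores")
  classes <- colnames(scores)
  if (is.null(classes)) {
    classes <- sort(unique(y_true))
    if (length(classes) != ncol(scores)) {
      stop("scores has ", ncol(scores), " columns but ", length(classes),
           " classes are present; name the columns")
    }
    colnames(scores) <- classes
  }
  aucs <- numeric(0)
  weights <- numeric(0)
  for (cl in classes) {
    pos <- y_true == cl
    if (!any(pos) || all(pos)) {
      warning("class '", cl, "' lacks positives or negatives; skipped")
      next
    }
    aucs <- c(aucs, binary_auc(scores[, cl], pos))
    weights <- c(weights, mean(pos))
  }
  if (length(aucs) == 0L) stop("no class with both positives and negatives")
  sum(aucs * weights / sum(weights))
}

#' Secondary classification metrics
#'
#' Plain accuracy plus prevalence-weighted precision, recall and F1. The
#' weights are the class frequencies in `y_true`; a precision of 0/0
#' (class never predicted) counts as 0.
#'
#' @inheritParams balanced_accuracy
#' @return list with `accuracy`, `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`.
#' @export
secondary_metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  classes <- sort(unique(y_true))
  w <- vapply(classes, function(cl) mean(y_true == cl), numeric(1))
  prec <- vapply(classes, function(cl) {
    denom <- sum(y_pred == cl)
    if (denom == 0L) 0 else sum(y_pred == cl & y_true == cl) / denom
  }, numeric(1))
  rec <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  list(accuracy = mean(y_true == y_pred),
       weighted_precision = sum(w * prec),
       weighted_recall = sum(w * rec),
       weighted_f1 = sum(w * f1))
}

#' Correlated t-test for repeated-split score comparison
#'
#' Paired t-test over per-split scores with the Nadeau-Bengio variance
#' correction for the train/test overlap of repeated resampling:
#' \deqn{t = \bar d / \sqrt{\hat\sigma^2_d (1/n + n_{test}/n_{train})}}
#' with a two-sided p-value from the Student t distribution on `n - 1`
#' degrees of freedom. As `test_fraction / train_fraction` tends to 0 the
#' statistic reduces to the classical paired t-test.
#'
#' Degenerate inputs: identical score vectors give `t = 0, p = 1`; zero
#' variance with a nonzero mean difference gives `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param scores_a,scores_b equal-length numeric vectors of paired
#'   per-split scores (length >= 2).
#' @param test_fraction,train_fraction the split proportions used to
#'   produce the scores (defaults 0.2 / 0.8).
#' @return list with `t`, `p_value`, `df`, `mean_diff`, `degenerate`.
#' @export
correlated_ttest <- function(scores_a, scores_b, test_fraction = 0.2,
                             train_fraction = 0.8) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2,
            test_fraction > 0, train_fraction > 0)
  d <- scores_a - scores_b
  n <- length(d)
  v <- stats::var(d)
  md <- mean(d)
  if (v == 0) {
    if (md == 0) {
      return(list(t = 0, p_value = 1, df = n - 1, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(t = sign(md) * Inf, p_value = 0, df = n - 1,
                mean_diff = md, degenerate = TRUE))
  }
  t_stat <- md / sqrt(v * (1 / n + test_fraction / train_fraction))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p_value = p, df = n - 1, mean_diff = md,
       degenerate = FALSE)
}

#' Evaluate a factor graph over repeated stratified splits
#'
#' Convenience driver for the full protocol: for every split in the plan
#' a fresh masked model is built from `fg`, trained on the training
#' portion and scored on the hold-out. Reports per-split and mean/SD
#' balanced accuracy and weighted one-vs-rest AUC plus the secondary
#' metrics.
#'
#' @param fg a `factor_graph`.
#' @param dataset an [expression_dataset()] with labels.
#' @param plan a [make_splits()] plan (built from the dataset labels when
#'   omitted).
#' @param cfg a [train_config()]; its seed is combined with each repeat's
#'   seed so repeats are independent.
#' @param ... passed to [build_model()].
#' @return a list of class `metrics_report` with `per_split` (data frame)
#'   and `summary` (mean and SD per metric).
#' @export
evaluate_factor_graph <- function(fg, dataset, plan = NULL,
                                  cfg = train_config(), ...) {
  stopifnot(inherits(fg, "factor_graph"),
            inherits(dataset, "expression_dataset"))
  if (is.null(dataset$labels)) stop("dataset has no labels")
  if (is.null(plan)) plan <- make_splits(dataset$labels, seed = cfg$seed)
  n_classes <- nlevels(dataset$labels)
  rows <- list()
  for (r in seq_along(plan$splits)) {
    sp <- plan$splits[[r]]
    tr <- subset_dataset(dataset, sp$train)
    te <- subset_dataset(dataset, sp$test)
    cfg_r <- cfg
    cfg_r$seed <- sp$seed
    model <- build_model(fg, n_classes = n_classes, seed = sp$seed, ...)
    model <- train_model(model, tr, cfg_r)
    proba <- predict_proba(model, te$values[, fg$gene_index, drop = FALSE])
    pred <- model$class_levels[max.col(proba, ties.method = "first")]
    sec <- secondary_metrics(te$labels, pred)
    rows[[r]] <- data.frame(
      split = r,
      b_acc = balanced_accuracy(te$labels, pred),
      w_auc = weighted_ovr_auc(as.character(te$labels), proba),
      accuracy = sec$accuracy,
      weighted_precision = sec$weighted_precision,
      weighted_recall = sec$weighted_recall,
      weighted_f1 = sec$weighted_f1)
  }
  per_split <- do.call(rbind, rows)
  metrics <- setdiff(colnames(per_split), "split")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mt) mean(per_split[[mt]]), numeric(1)),
    sd = vapply(metrics, function(mt) stats::sd(per_split[[mt]]), numeric(1)),
    row.names = NULL)
  structure(list(per_split = per_split, summary = summary,
                 plan = plan),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics over", nrow(x$per_split), "splits:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Subset an expression dataset by sample index
#'
#' @param dataset an [expression_dataset()].
#' @param idx integer vector of sample indices.
#' @return the subset [expression_dataset()] (label levels preserved).
#' @export
subset_dataset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "expression_dataset"))
  expression_dataset(dataset$values[idx, , drop = FALSE],
                     gene_names = dataset$gene_names,
                     sample_ids = dataset$sample_ids[idx],
                     labels = if (!is.null(dataset$labels))
                       factor(dataset$labels[idx],
                              levels = levels(dataset$labels)))
}
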