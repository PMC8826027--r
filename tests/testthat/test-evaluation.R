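test_that("stratified splits hit per-class test counts and are reproducible", {
  y <- factor(rep(c("a", "b"), each = 50))
  plan <- make_splits(y, n_repeats = 3, seed = 11)
  for (sp in plan$splits) {
    expect_equal(as.vector(table(y[sp$test])), c(10, 10))
    expect_setequal(c(sp$train, sp$test), 1:100)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  plan2 <- make_splits(y, n_repeats = 3, seed = 11)
  expect_identical(lapply(plan$splits, `[[`, "test"),
                   lapply(plan2$splits, `[[`, "test"))

  # unbalanced three-class case: per-class counts within 1 of 0.2 * n_c
  y3 <- factor(c(rep("a", 50), rep("b", 33), rep("c", 14)))
  plan3 <- make_splits(y3, n_repeats = 5, seed = 2)
  for (sp in plan3$splits) {
    cnt <- table(y3[sp$test])
    for (cl in names(cnt)) {
      expect_lte(abs(cnt[[cl]] - 0.2 * sum(y3 == cl)), 1)
    }
  }
  expect_error(make_splits(factor(c("a", "a", "b"))), "fewer than 2")
})

test_that("balanced accuracy is the unweighted mean of per-class recall", {
  # constant prediction on 11 represented classes
  y <- rep(paste0("k", 1:11), times = 3)
  expect_equal(balanced_accuracy(y, rep("k1", length(y))), 100 / 11)
  expect_equal(balanced_accuracy(c("a", "b"), c("a", "b")), 100)
  # hand-computed 2x2 confusion: TP=3, FN=1, TN=2, FP=2
  y_true <- c(rep("pos", 4), rep("neg", 4))
  y_pred <- c("pos", "pos", "pos", "neg", "pos", "pos", "neg", "neg")
  expect_equal(balanced_accuracy(y_true, y_pred), 62.5)
  expect_error(balanced_accuracy(c("a", "b"), c("a")), "length")
})

test_that("weighted one-vs-rest AUC matches brute-force pair counting", {
  y <- c("a", "a", "b", "b", "c", "c")
  set.seed(13)
  scores <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  got <- weighted_ovr_auc(y, scores)
  oracle <- 0
  for (cl in c("a", "b", "c")) {
    oracle <- oracle + (1 / 3) * oracle_pair_auc(scores[, cl], y == cl)
  }
  expect_equal(got, oracle)

  # constant scores are uninformative; perfect scores are perfect
  expect_equal(weighted_ovr_auc(y, matrix(1, 6, 3,
                                          dimnames = list(NULL, c("a", "b", "c")))),
               0.5)
  perfect <- matrix(0, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  perfect[cbind(1:6, match(y, c("a", "b", "c")))] <- 1
  expect_equal(weighted_ovr_auc(y, perfect), 1)

  # invariance under strictly monotone score transforms
  expect_equal(weighted_ovr_auc(y, exp(2 * scores)), got)

  # degenerate class skipped with renormalized weights
  y2 <- c("a", "a", "b", "b", "b", "b")
  s2 <- scores
  expect_warning(got2 <- weighted_ovr_auc(y2, s2), "skipped")
  oa <- oracle_pair_auc(s2[, "a"], y2 == "a")
  ob <- oracle_pair_auc(s2[, "b"], y2 == "b")
  expect_equal(got2, (2 / 6 * oa + 4 / 6 * ob) / 1)
})

test_that("weighted AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  s <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  got <- weighted_ovr_auc(y, s)
  ref <- 0
  for (cl in c("a", "b")) {
    r <- pROC::roc(response = as.integer(y == cl), predictor = s[, cl],
                   quiet = TRUE, direction = "<")
    ref <- ref + mean(y == cl) * as.numeric(pROC::auc(r))
  }
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("secondary metrics follow their standard prevalence-weighted definitions", {
  expect_equal(secondary_metrics(c("a", "b"), c("a", "b")),
               list(accuracy = 1, weighted_precision = 1,
                    weighted_recall = 1, weighted_f1 = 1))
  allwrong <- secondary_metrics(c("a", "a", "b"), c("b", "b", "a"))
  expect_equal(allwrong$accuracy, 0)
  # hand computation on a small table
  y_true <- c("a", "a", "a", "b", "b", "c")
  y_pred <- c("a", "a", "b", "b", "b", "a")
  sm <- secondary_metrics(y_true, y_pred)
  prec <- c(a = 2 / 3, b = 2 / 3, c = 0)
  rec <- c(a = 2 / 3, b = 1, c = 0)
  w <- c(a = 3 / 6, b = 2 / 6, c = 1 / 6)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  expect_equal(sm$accuracy, 4 / 6)
  expect_equal(sm$weighted_precision, sum(w * prec))
  expect_equal(sm$weighted_recall, sum(w * rec))
  expect_equal(sm$weighted_f1, sum(w * f1))
})

test_that("correlated t-test handles degenerate and random inputs", {
  x <- c(0.7, 0.8, 0.75, 0.72, 0.77)
  r <- correlated_ttest(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  r2 <- correlated_ttest(x + 1, x)
  expect_true(r2$degenerate)
  expect_equal(r2$p_value, 0)

  # stepwise arithmetic oracle on random paired scores
  set.seed(21)
  a <- runif(5); b <- runif(5)
  got <- correlated_ttest(a, b, test_fraction = 0.2, train_fraction = 0.8)
  d <- a - b
  n <- 5
  t_oracle <- mean(d) / sqrt(var(d) * (1 / n + 0.2 / 0.8))
  p_oracle <- 2 * pt(-abs(t_oracle), df = n - 1)
  expect_equal(got$t, t_oracle)
  expect_equal(got$p_value, p_oracle)
  expect_equal(got$df, 4)
})

test_that("correlated t-test reduces to the classical paired t-test", {
  set.seed(8)
  a <- rnorm(10); b <- rnorm(10)
  got <- correlated_ttest(a, b, test_fraction = 1e-12, train_fraction = 1)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("the repeated-split driver reports coherent summaries", {
  spec <- synthetic_spec(n_genes = 30, n_complexes = 3,
                         complex_size_range = c(4, 6), p_in = 1, p_out = 0,
                         overlap_fraction = 0, n_samples = 60,
                         n_classes = 2, seed = 17)
  net <- generate_planted_network(spec)
  ds <- generate_expression_phenotype(spec, net$ground_truth)
  fg <- build_factor_graph(net$ground_truth, ds$gene_names)
  rep <- evaluate_factor_graph(
    fg, ds, plan = make_splits(ds$labels, n_repeats = 2, seed = 3),
    cfg = train_config(max_epochs = 30, learning_rate = 1e-2, seed = 3))
  expect_equal(nrow(rep$per_split), 2)
  expect_true(all(rep$per_split$b_acc >= 0 & rep$per_split$b_acc <= 100))
  expect_true(all(rep$per_split$w_auc >= 0 & rep$per_split$w_auc <= 1))
  expect_equal(rep$summary$mean[rep$summary$metric == "b_acc"],
               mean(rep$per_split$b_acc))
})
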