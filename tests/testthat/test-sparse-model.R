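toy_fg <- function() {
  build_factor_graph(
    clustering(list(c1 = c("g1", "g2", "g3"), c2 = c("g3", "g4"))),
    paste0("g", 1:6))
}

test_that("initialization is masked, bounded and reproducible", {
  fg <- toy_fg()
  m <- build_model(fg, n_classes = 2, seed = 7)
  lim1 <- sqrt(6 / (6 + 2))
  expect_true(all(m$W1[m$mask == 0] == 0))
  expect_true(all(abs(m$W1[m$mask == 1]) <= lim1))
  expect_true(all(m$W1[m$mask == 1] != 0))
  m2 <- build_model(fg, n_classes = 2, seed = 7)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$W2, m2$W2)
  expect_error(build_model(fg, n_classes = 1), "n_classes")
  # nonzero trainable first-layer weights match the edge count
  expect_equal(sum(m$mask), count_edges(fg))
})

test_that("complex activities depend only on member genes", {
  fg <- toy_fg()
  m <- build_model(fg, n_classes = 3, seed = 1)
  X <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("g", 1:6)))
  h0 <- model_forward(m, X)$activities
  X2 <- X
  X2[, c("g5", "g6")] <- X2[, c("g5", "g6")] + 100  # outside both complexes
  h1 <- model_forward(m, X2)$activities
  expect_identical(h0, h1)
  X3 <- X
  X3[, "g4"] <- X3[, "g4"] + 1  # member of c2 only
  h2 <- model_forward(m, X3)$activities
  expect_identical(h0[, "c1"], h2[, "c1"])
  expect_false(all(h0[, "c2"] == h2[, "c2"]))
})

test_that("forward pass matches hand-computed arithmetic", {
  fg <- build_factor_graph(clustering(list(c1 = c("g1", "g2"))),
                           c("g1", "g2", "g3"))
  m <- build_model(fg, n_classes = 2, activation = "identity", seed = 1)
  m <- netfactor:::set_model_weights(
    m, W1 = matrix(c(0.5, -2, 0), 3, 1), b1 = 0.25,
    W2 = matrix(c(1, -1), 1, 2), b2 = c(0, 0.5))
  x <- matrix(c(3, 1, 10), 1, 3)  # g3 masked out
  out <- model_forward(m, x)
  h <- 0.5 * 3 - 2 * 1 + 0.25
  expect_equal(out$activities[1, 1], h, ignore_attr = TRUE)
  expect_equal(out$logits[1, ], c(h, -h + 0.5), ignore_attr = TRUE)

  # zero input without biases gives uniform class probabilities
  m0 <- build_model(fg, n_classes = 2, use_bias = FALSE, seed = 2)
  p <- model_forward(m0, matrix(0, 4, 3))$proba
  expect_equal(p, matrix(0.5, 4, 2))
})

test_that("probabilities are a softmax with its invariances", {
  fg <- toy_fg()
  m <- build_model(fg, n_classes = 3, seed = 3)
  X <- matrix(rnorm(30), 5, 6)
  p <- predict_proba(m, X)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)

  logits <- matrix(rnorm(8), 4, 2)
  expect_equal(netfactor:::softmax_rows(logits),
               netfactor:::softmax_rows(logits + 5))
  # two-class probability is the logistic of the logit difference
  expect_equal(netfactor:::softmax_rows(logits)[, 1],
               stats::plogis(logits[, 1] - logits[, 2]))
})

test_that("training reduces loss, respects max_epochs = 0 and preserves the mask", {
  spec <- synthetic_spec(n_genes = 20, n_complexes = 2,
                         complex_size_range = c(4, 6), p_in = 1, p_out = 0,
                         overlap_fraction = 0, n_samples = 40,
                         n_classes = 2, seed = 5)
  net <- generate_planted_network(spec)
  ds <- generate_expression_phenotype(spec, net$ground_truth)
  fg <- build_factor_graph(net$ground_truth, ds$gene_names)
  m <- build_model(fg, n_classes = 2, seed = 5)

  m0 <- train_model(m, ds, train_config(max_epochs = 0, seed = 5))
  expect_identical(m0$W1, m$W1)
  expect_equal(nrow(m0$history), 0)

  cfg <- train_config(max_epochs = 40, learning_rate = 1e-2, seed = 5)
  mt <- train_model(m, ds, cfg)
  expect_lt(min(mt$history$train_loss), mt$history$train_loss[1])
  expect_true(all(mt$W1[mt$mask == 0] == 0))
  expect_lte(nrow(mt$history), 40)
  # determinism of the full trajectory
  mt2 <- train_model(m, ds, cfg)
  expect_identical(mt$history, mt2$history)
  expect_identical(mt$W1, mt2$W1)
})

test_that("a masked model equals a dense model on the selected gene subset", {
  # one complex of 4 genes inside a 12-gene input; the dense counterpart
  # sees only those 4 genes. With identical initial weights the whole
  # training trajectory must coincide.
  genes <- paste0("g", 1:12)
  members <- c("g2", "g5", "g7", "g11")
  fg_masked <- build_factor_graph(clustering(list(c1 = members)), genes)
  fg_dense <- fully_connected_factor_graph(members, 1)

  set.seed(42)
  m <- 48
  z <- rnorm(m)
  y <- factor(ifelse(z + rnorm(m, sd = 0.3) > 0, "hi", "lo"))
  X <- matrix(rnorm(m * 12, sd = 0.5), m, 12, dimnames = list(NULL, genes))
  X[, members] <- X[, members] + z
  ds_full <- expression_dataset(X, labels = y)
  ds_sub <- expression_dataset(X[, members], labels = y)

  mk <- build_model(fg_masked, n_classes = 2, seed = 9)
  md <- build_model(fg_dense, n_classes = 2, seed = 9)
  md <- netfactor:::set_model_weights(
    md, W1 = mk$W1[members, , drop = FALSE], b1 = mk$b1, W2 = mk$W2,
    b2 = mk$b2)

  cfg <- train_config(max_epochs = 25, batch_size = 8,
                      learning_rate = 1e-3, seed = 9)
  tk <- train_model(mk, ds_full, cfg)
  td <- train_model(md, ds_sub, cfg)
  expect_equal(tk$history, td$history, tolerance = 1e-10)
  expect_equal(tk$W1[members, ], td$W1[, 1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tk$W2, td$W2, tolerance = 1e-10)
  expect_true(all(tk$W1[setdiff(genes, members), ] == 0))
})

test_that("training fails loudly when a class is missing from the training portion", {
  fg <- toy_fg()
  X <- matrix(rnorm(36), 6, 6, dimnames = list(NULL, paste0("g", 1:6)))
  ds <- expression_dataset(X, labels = factor(rep("a", 6),
                                              levels = c("a", "b")))
  m <- build_model(fg, n_classes = 2, seed = 1)
  expect_error(train_model(m, ds, train_config(max_epochs = 2, seed = 1)),
               "absent from the training portion")
})

test_that("a fully connected mask reduces to an ordinary two-layer perceptron", {
  genes <- paste0("g", 1:5)
  fg <- fully_connected_factor_graph(genes, 3)
  m <- build_model(fg, n_classes = 2, seed = 4)
  expect_true(all(m$mask == 1))
  expect_equal(sum(m$W1 != 0), 15)
})
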