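#' Fully connected factor graph
#'
#' Convenience constructor for the dense counterpart of a clustered
#' factor graph: every gene is connected to every one of `l` hidden
#' units. Used for baseline comparisons and for reducing the masked model
#' to an ordinary two-layer perceptron.
#'
#' @param gene_index ordered character vector of gene names.
#' @param l number of hidden units.
#' @return a `factor_graph` with origin `"fully_connected"`.
#' @export
fully_connected_factor_graph <- function(gene_index, l) {
  gene_index <- as.character(gene_index)
  stopifnot(length(gene_index) >= 1L, l >= 1L)
  complex_names <- paste0("h_", seq_len(l))
  new_factor_graph(gene_index, complex_names,
                   cbind(gene = rep(gene_index, times = l),
                         complex = rep(complex_names,
                                       each = length(gene_index))),
                   origin = "fully_connected")
}

# k x l 0/1 mask matrix from a factor graph
membership_mask <- function(fg) {
  k <- length(fg$gene_index)
  l <- length(fg$complex_names)
  mask <- matrix(0, k, l, dimnames = list(fg$gene_index, fg$complex_names))
  gi <- match(fg$memberships[, "gene"], fg$gene_index)
  ci <- match(fg$memberships[, "complex"], fg$complex_names)
  mask[cbind(gi, ci)] <- 1
  mask
}

#' Training configuration
#'
#' Defaults follow the protocol used throughout the package: Adam with
#' learning rate 1e-4, mini-batches of 32, up to 500 epochs, a stratified
#' quarter of the training data held out for early stopping with patience
#' 20 and best-weights restore.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param validation_fraction fraction of the training data held out for
#'   early stopping; 0 disables early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling the validation split and batch
#'   shuffling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         max_epochs = 500L, validation_fraction = 0.25,
                         patience = 20L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            validation_fraction >= 0, validation_fraction < 1,
            patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a masked two-layer model from a factor graph
#'
#' The model computes one activity per complex from the expression of its
#' member genes only (a masked k x l first layer followed by the chosen
#' nonlinearity), then maps the activities to class scores through a
#' fully connected l x n_classes output layer with softmax. Weights are
#' initialized Xavier-uniform from the dense layer dimensions and then
#' multiplied by the membership mask, so masked positions start (and
#' remain) exactly zero.
#'
#' @param fg a `factor_graph` defining the first-layer mask.
#' @param n_classes number of phenotype classes (>= 2).
#' @param activation nonlinearity of the complex activities: `"relu"`
#'   (default), `"identity"` or `"tanh"`.
#' @param use_bias logical; include bias terms in both layers (biases are
#'   initialized at zero and are not part of the edge count).
#' @param seed integer seed for the initialization.
#' @param xavier_fan `"dense"` (default) computes the Xavier bound from
#'   the full `(k, l)` shape; `"per_complex"` uses each complex's own
#'   fan-in.
#' @return an untrained object of class `sparse_model`.
#' @export
build_model <- function(fg, n_classes, activation = c("relu", "identity",
                                                      "tanh"),
                        use_bias = TRUE, seed = 1L,
                        xavier_fan = c("dense", "per_complex")) {
  stopifnot(inherits(fg, "factor_graph"))
  activation <- match.arg(activation)
  xavier_fan <- match.arg(xavier_fan)
  if (n_classes < 2) stop("n_classes must be >= 2")
  k <- length(fg$gene_index)
  l <- length(fg$complex_names)
  mask <- membership_mask(fg)
  withr_seed(seed, {
    lim1 <- sqrt(6 / (k + l))
    W1 <- matrix(stats::runif(k * l, -lim1, lim1), k, l,
                 dimnames = dimnames(mask))
    if (xavier_fan == "per_complex") {
      fan_in <- pmax(colSums(mask), 1)
      lims <- sqrt(6 / (fan_in + 1))
      W1 <- sweep(W1 / lim1, 2L, lims, `*`)
    }
    W1 <- W1 * mask
    lim2 <- sqrt(6 / (l + n_classes))
    W2 <- matrix(stats::runif(l * n_classes, -lim2, lim2), l, n_classes,
                 dimnames = list(fg$complex_names, NULL))
  })
  structure(list(fg = fg, mask = mask,
                 W1 = W1, b1 = numeric(l),
                 W2 = W2, b2 = numeric(n_classes),
                 n_classes = as.integer(n_classes),
                 activation = activation, use_bias = use_bias,
                 class_levels = NULL,
                 history = NULL, best_epoch = NULL),
            class = "sparse_model")
}

#' @export
print.sparse_model <- function(x, ...) {
  cat("sparse_model: ", nrow(x$W1), " genes -> ", ncol(x$W1),
      " complexes -> ", x$n_classes, " classes (", x$activation,
      "), ", sum(x$mask), " first-layer weights\n", sep = "")
  if (!is.null(x$best_epoch)) cat("trained; best epoch", x$best_epoch, "\n")
  invisible(x)
}

apply_activation <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         identity = z,
         tanh = tanh(z))
}

activation_grad <- function(z, h, activation) {
  switch(activation,
         relu = (z > 0) * 1,
         identity = array(1, dim(z)),
         tanh = 1 - h^2)
}

#' Forward pass of the masked model
#'
#' @param model a `sparse_model`.
#' @param X numeric m x k matrix whose columns follow the model's gene
#'   index (checked by name when column names are present).
#' @return list with `activities` (m x l), `logits` (m x n_classes) and
#'   `proba` (softmax of the logits).
#' @export
model_forward <- function(model, X) {
  stopifnot(inherits(model, "sparse_model"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W1)) {
    stop("X has ", ncol(X), " columns; model expects ", nrow(model$W1))
  }
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model$fg$gene_index)) {
    stop("column order of X does not match the model's gene index")
  }
  Z1 <- X %*% model$W1
  if (model$use_bias) Z1 <- sweep(Z1, 2L, model$b1, `+`)
  H <- apply_activation(Z1, model$activation)
  logits <- H %*% model$W2
  if (model$use_bias) logits <- sweep(logits, 2L, model$b2, `+`)
  list(activities = H, logits = logits, proba = softmax_rows(logits))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predicted class probabilities
#'
#' @inheritParams model_forward
#' @return m x n_classes matrix of probabilities (rows sum to 1); columns
#'   are named by the class levels when the model has been trained.
#' @export
predict_proba <- function(model, X) {
  p <- model_forward(model, X)$proba
  if (!is.null(model$class_levels)) colnames(p) <- model$class_levels
  p
}

#' Predicted class labels
#'
#' @inheritParams model_forward
#' @return character (or factor-level) vector of argmax classes.
#' @export
predict_class <- function(model, X) {
  p <- predict_proba(model, X)
  idx <- max.col(p, ties.method = "first")
  if (!is.null(model$class_levels)) model$class_levels[idx] else idx
}

cross_entropy <- function(proba, y_idx) {
  eps <- 1e-12
  -mean(log(pmax(proba[cbind(seq_along(y_idx), y_idx)], eps)))
}

# internal: overwrite weights (used to align two models on a shared
# initialization, e.g. when comparing a masked model with its dense
# counterpart on the selected gene subset)
set_model_weights <- function(model, W1 = NULL, b1 = NULL, W2 = NULL,
                              b2 = NULL) {
  if (!is.null(W1)) {
    stopifnot(all(dim(W1) == dim(model$W1)))
    model$W1 <- W1 * model$mask
  }
  if (!is.null(b1)) model$b1 <- b1
  if (!is.null(W2)) model$W2 <- W2
  if (!is.null(b2)) model$b2 <- b2
  model
}

#' Train a masked model
#'
#' Mini-batch Adam on the multinomial cross-entropy, with a stratified
#' hold-out of `validation_fraction` of the supplied data for early
#' stopping and best-weights restore. The first-layer gradient is
#' multiplied by the membership mask at every step, so weights outside
#' the mask remain exactly zero throughout training. All randomness (the
#' validation split and the per-epoch batch shuffling) is derived from
#' `cfg$seed`, making training deterministic in single-threaded BLAS.
#'
#' @param model an untrained (or previously trained) `sparse_model`.
#' @param dataset an [expression_dataset()] with labels.
#' @param cfg a [train_config()].
#' @return the trained `sparse_model`, with `history` (a data frame of
#'   per-epoch train/validation loss) and `best_epoch` filled in.
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "sparse_model"),
            inherits(dataset, "expression_dataset"),
            inherits(cfg, "train_config"))
  if (is.null(dataset$labels)) stop("dataset has no labels")
  y <- dataset$labels
  levels_y <- levels(y)
  if (length(levels_y) != model$n_classes) {
    stop("label vocabulary has ", length(levels_y),
         " classes; model expects ", model$n_classes)
  }
  X <- dataset$values
  if (!identical(colnames(X), model$fg$gene_index)) {
    if (!all(model$fg$gene_index %in% colnames(X))) {
      stop("dataset is missing genes required by the model")
    }
    X <- X[, model$fg$gene_index, drop = FALSE]
  }
  y_idx <- as.integer(y)
  m <- nrow(X)
  model$class_levels <- levels_y

  withr_seed(cfg$seed, {
    # stratified validation split
    if (cfg$validation_fraction > 0) {
      val_idx <- integer(0)
      for (c_i in seq_along(levels_y)) {
        members <- which(y_idx == c_i)
        n_val <- round(cfg$validation_fraction * length(members))
        if (n_val > 0) {
          val_idx <- c(val_idx, sample(members, n_val))
        }
      }
      val_idx <- sort(val_idx)
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(m), val_idx)
    if (!all(seq_along(levels_y) %in% y_idx[tr_idx])) {
      missing <- levels_y[!seq_along(levels_y) %in% y_idx[tr_idx]]
      stop("class absent from the training portion: ",
           paste(missing, collapse = ", "))
    }
    X_tr <- X[tr_idx, , drop = FALSE]
    y_tr <- y_idx[tr_idx]
    X_val <- X[val_idx, , drop = FALSE]
    y_val <- y_idx[val_idx]
    n_tr <- length(tr_idx)
    Y_tr_onehot <- matrix(0, n_tr, model$n_classes)
    Y_tr_onehot[cbind(seq_len(n_tr), y_tr)] <- 1

    # Adam state
    opt <- list(t = 0)
    for (nm in c("W1", "b1", "W2", "b2")) {
      opt[[paste0("m_", nm)]] <- model[[nm]] * 0
      opt[[paste0("v_", nm)]] <- model[[nm]] * 0
    }
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    adam_step <- function(theta, g, nm) {
      opt[[paste0("m_", nm)]] <<- beta1 * opt[[paste0("m_", nm)]] +
        (1 - beta1) * g
      opt[[paste0("v_", nm)]] <<- beta2 * opt[[paste0("v_", nm)]] +
        (1 - beta2) * g^2
      mhat <- opt[[paste0("m_", nm)]] / (1 - beta1^opt$t)
      vhat <- opt[[paste0("v_", nm)]] / (1 - beta2^opt$t)
      theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }

    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(loss = Inf, epoch = 0L,
                 W1 = model$W1, b1 = model$b1,
                 W2 = model$W2, b2 = model$b2)
    wait <- 0L

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = cfg$batch_size)
      for (s in starts) {
        rows <- perm[s:min(s + cfg$batch_size - 1L, n_tr)]
        Xb <- X_tr[rows, , drop = FALSE]
        Yb <- Y_tr_onehot[rows, , drop = FALSE]
        B <- length(rows)

        Z1 <- Xb %*% model$W1
        if (model$use_bias) Z1 <- sweep(Z1, 2L, model$b1, `+`)
        H <- apply_activation(Z1, model$activation)
        logits <- H %*% model$W2
        if (model$use_bias) logits <- sweep(logits, 2L, model$b2, `+`)
        P <- softmax_rows(logits)

        dlogits <- (P - Yb) / B
        gW2 <- crossprod(H, dlogits)
        dH <- dlogits %*% t(model$W2)
        dZ1 <- dH * activation_grad(Z1, H, model$activation)
        gW1 <- crossprod(Xb, dZ1) * model$mask

        opt$t <- opt$t + 1
        model$W1 <- adam_step(model$W1, gW1, "W1") * model$mask
        model$W2 <- adam_step(model$W2, gW2, "W2")
        if (model$use_bias) {
          model$b1 <- adam_step(model$b1, colSums(dZ1), "b1")
          model$b2 <- adam_step(model$b2, colSums(dlogits), "b2")
        }
      }

      train_loss <- cross_entropy(model_forward(model, X_tr)$proba, y_tr)
      if (!is.finite(train_loss)) {
        stop("non-finite training loss at epoch ", epoch)
      }
      val_loss <- if (length(val_idx) > 0L) {
        cross_entropy(model_forward(model, X_val)$proba, y_val)
      } else NA_real_
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss))

      monitor <- if (is.na(val_loss)) train_loss else val_loss
      if (monitor < best$loss) {
        best <- list(loss = monitor, epoch = epoch,
                     W1 = model$W1, b1 = model$b1,
                     W2 = model$W2, b2 = model$b2)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }

    if (best$epoch > 0L) {
      model$W1 <- best$W1; model$b1 <- best$b1
      model$W2 <- best$W2; model$b2 <- best$b2
    }
    model$history <- history
    model$best_epoch <- best$epoch
  })
  model
}
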