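# Softmax deep neural network closing the swarm-selection pipeline:
# cross-entropy + weight decay, Adam, inverted dropout after each hidden
# layer, and a fine-tuning phase during which only the softmax head moves.

#' DNN classifier configuration
#'
#' Defaults mirror the published classifier: hidden sizes 2250 and 500 with a
#' 2-unit softmax head, 50 epochs at batch size 10, with the last 20 epochs
#' fine-tuning the softmax head only. Dropout rate and learning rate are not
#' fixed by the source description; the defaults here are conventional values.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param n_classes Number of classes (2 for the problems addressed here).
#' @param dropout_rate Drop probability in `[0, 1)` after each hidden layer.
#' @param weight_decay Non-negative L2 penalty on weights.
#' @param epochs Total training epochs.
#' @param fine_tune_epochs Final epochs during which hidden layers are frozen.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed.
#' @return A list of class `dnn_config`.
#' @export
dnn_config <- function(hidden_sizes = c(2250L, 500L), n_classes = 2L,
                       dropout_rate = 0.5, weight_decay = 1e-4, epochs = 50L,
                       fine_tune_epochs = 20L, batch_size = 10L,
                       learning_rate = 1e-3, seed = 1L) {
  if (length(hidden_sizes) < 1L) abort_arg("`hidden_sizes` must be non-empty")
  hidden_sizes <- vapply(hidden_sizes, check_count, integer(1L), name = "hidden_sizes")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (dropout_rate < 0 || dropout_rate >= 1) abort_arg("`dropout_rate` must be in [0, 1)")
  epochs <- check_count(epochs, "epochs")
  fine_tune_epochs <- check_count(fine_tune_epochs, "fine_tune_epochs", min = 0L)
  if (fine_tune_epochs > epochs) abort_arg("`fine_tune_epochs` must not exceed `epochs`")
  structure(list(hidden_sizes = hidden_sizes, n_classes = n_classes,
                 dropout_rate = as.numeric(dropout_rate),
                 weight_decay = check_scalar(weight_decay, "weight_decay", lower = 0),
                 epochs = epochs, fine_tune_epochs = fine_tune_epochs,
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = check_scalar(learning_rate, "learning_rate", lower = 1e-12),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "dnn_config")
}

init_dnn <- function(cfg, input_dim) {
  sizes <- c(input_dim, cfg$hidden_sizes, cfg$n_classes)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
      sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  structure(list(cfg = cfg, input_dim = input_dim, sizes = sizes,
                 params = params, trained = FALSE, loss_trace = numeric(0)),
            class = "dnn_model")
}

# Forward pass; `drop_masks` (list or NULL) applies inverted dropout after
# each hidden activation during training.
dnn_forward <- function(model, X, drop_masks = NULL) {
  n_w <- length(model$sizes) - 1L
  A <- vector("list", n_w + 1L)
  Z <- vector("list", n_w + 1L)
  A[[1L]] <- X
  for (l in seq_len(n_w)) {
    Z[[l + 1L]] <- add_bias_rows(A[[l]] %*% model$params[[paste0("W", l)]],
                                 model$params[[paste0("b", l)]])
    if (l < n_w) {
      act <- relu(Z[[l + 1L]])
      if (!is.null(drop_masks)) act <- act * drop_masks[[l]]
      A[[l + 1L]] <- act
    } else {
      A[[l + 1L]] <- softmax_rows(Z[[l + 1L]])
    }
  }
  list(A = A, Z = Z)
}

dnn_cost_grads <- function(model, X, y, drop_masks = NULL) {
  cfg <- model$cfg
  n <- nrow(X)
  n_w <- length(model$sizes) - 1L
  fw <- dnn_forward(model, X, drop_masks)
  prob <- fw$A[[n_w + 1L]]
  decay_sum <- 0
  for (l in seq_len(n_w)) decay_sum <- decay_sum + sum(model$params[[paste0("W", l)]]^2)
  cost <- cross_entropy(prob, y) + cfg$weight_decay / 2 * decay_sum
  grads <- lapply(model$params, function(x) array(0, dim = dim(x) %||% length(x)))
  dZ <- (prob - one_hot(y, cfg$n_classes)) / n
  for (l in rev(seq_len(n_w))) {
    grads[[paste0("W", l)]] <- t(fw$A[[l]]) %*% dZ +
      cfg$weight_decay * model$params[[paste0("W", l)]]
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(model$params[[paste0("W", l)]])
      if (!is.null(drop_masks)) dA <- dA * drop_masks[[l - 1L]]
      dZ <- dA * (fw$Z[[l]] > 0)
    }
  }
  list(cost = cost, grads = grads)
}

#' Train the softmax DNN classifier
#'
#' Minimizes cross-entropy plus weight decay with Adam. During the final
#' `fine_tune_epochs` only the softmax head's weights and bias are updated
#' (hidden layers frozen). Dropout is applied after each hidden layer during
#' training only.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer labels `0 .. n_classes-1`; both classes must appear.
#' @param cfg A [dnn_config()].
#' @return A trained `dnn_model` with a per-epoch `loss_trace`.
#' @export
train_dnn <- function(features, labels, cfg = dnn_config()) {
  if (!inherits(cfg, "dnn_config")) abort_arg("`cfg` must be a dnn_config")
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (nrow(X) != length(y)) abort_arg("`labels` length must equal nrow(features)")
  if (length(unique(y)) < 2L) abort_arg("training data must contain both classes")
  if (min(table(y)) < 2L) abort_arg("at least 2 samples per class are required")
  with_seed(cfg$seed, {
    model <- init_dnn(cfg, ncol(X))
    opt <- adam_init(model$params)
    n <- nrow(X)
    bs <- min(cfg$batch_size, n)
    n_w <- length(model$sizes) - 1L
    head_names <- paste0(c("W", "b"), n_w)
    trace <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      fine_tune <- epoch > cfg$epochs - cfg$fine_tune_epochs
      idx <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        take <- idx[start:min(start + bs - 1L, n)]
        Xb <- X[take, , drop = FALSE]
        masks <- NULL
        if (cfg$dropout_rate > 0) {
          keep <- 1 - cfg$dropout_rate
          masks <- lapply(cfg$hidden_sizes, function(h) {
            matrix(stats::rbinom(length(take) * h, 1L, keep) / keep,
                   length(take), h)
          })
        }
        cg <- dnn_cost_grads(model, Xb, y[take], masks)
        if (!is.finite(cg$cost)) abort_training(sprintf("non-finite loss at epoch %d", epoch))
        upd_names <- if (fine_tune) head_names else names(model$params)
        step <- adam_step(model$params[upd_names], cg$grads[upd_names], opt,
                          cfg$learning_rate)
        model$params[upd_names] <- step$params
        opt <- step$state
      }
      trace[epoch] <- dnn_cost_grads(model, X, y)$cost
      if (!is.finite(trace[epoch])) abort_training(sprintf("non-finite loss at epoch %d", epoch))
    }
    model$loss_trace <- trace
    model$trained <- TRUE
    model
  })
}

#' Predict class probabilities and labels
#'
#' Dropout is disabled at inference. Ties in the probability row are broken
#' toward the lower class index.
#'
#' @param model A trained `dnn_model`.
#' @param features Numeric matrix with the training feature width.
#' @return List with `prob` (row-stochastic matrix) and `labels` (integer
#'   argmax labels, `0`-based).
#' @export
predict_dnn <- function(model, features) {
  if (!inherits(model, "dnn_model")) abort_arg("`model` must be a dnn_model")
  if (!isTRUE(model$trained)) abort_state("model has not been trained")
  X <- as.matrix(features)
  if (ncol(X) != model$input_dim) {
    abort_arg(sprintf("feature width %d != model input size %d",
                      ncol(X), model$input_dim))
  }
  fw <- dnn_forward(model, X)
  prob <- fw$A[[length(model$sizes)]]
  list(prob = prob, labels = max.col(prob, ties.method = "first") - 1L)
}

#' @export
predict.dnn_model <- function(object, newdata, ...) {
  predict_dnn(object, newdata)
}
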