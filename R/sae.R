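# Sparse autoencoder: mean squared reconstruction error + weight decay +
# Bernoulli-KL sparsity penalty on the bottleneck's mean activation, trained
# with Adam. Hidden units are ReLU; the reconstruction layer is linear so that
# centred (z-scored) signals can be reproduced.

#' Sparse autoencoder configuration
#'
#' Defaults follow the published operating point: sparsity target `p = 0.08`,
#' weight decay `lambda = 0.01`, sparsity weight `beta = 4`, 50 training
#' iterations at batch size 10.
#'
#' @param layer_sizes Integer vector of layer widths, input first and a
#'   reconstruction layer of the same width last; the narrowest interior layer
#'   is the bottleneck.
#' @param weight_decay Non-negative L2 penalty `lambda` on all weights.
#' @param sparse_penalty Non-negative sparsity weight `beta`.
#' @param sparsity_target Target mean activation `p` in (0, 1).
#' @param iterations Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed (initialization and batch order).
#' @return A list of class `sae_config`.
#' @export
sae_config <- function(layer_sizes, weight_decay = 0.01, sparse_penalty = 4,
                       sparsity_target = 0.08, iterations = 50L,
                       batch_size = 10L, learning_rate = 1e-3, seed = 1L) {
  if (length(layer_sizes) < 3L) abort_arg("`layer_sizes` needs at least input, bottleneck, output")
  layer_sizes <- vapply(layer_sizes, check_count, integer(1L), name = "layer_sizes")
  if (layer_sizes[1L] != layer_sizes[length(layer_sizes)]) {
    abort_arg("first and last layer sizes must match (reconstruction)")
  }
  # the narrowest interior layer is the bottleneck; over-complete bottlenecks
  # (wider than the input, like the published 9000-unit layer) are permitted
  interior <- layer_sizes[-c(1L, length(layer_sizes))]
  check_scalar(weight_decay, "weight_decay", lower = 0)
  check_scalar(sparse_penalty, "sparse_penalty", lower = 0)
  if (sparsity_target <= 0 || sparsity_target >= 1) {
    abort_arg("`sparsity_target` must lie strictly in (0, 1)")
  }
  structure(list(layer_sizes = layer_sizes,
                 bottleneck = 1L + which.min(interior),
                 weight_decay = as.numeric(weight_decay),
                 sparse_penalty = as.numeric(sparse_penalty),
                 sparsity_target = as.numeric(sparsity_target),
                 iterations = check_count(iterations, "iterations"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = check_scalar(learning_rate, "learning_rate", lower = 1e-12),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "sae_config")
}

# He-scaled Gaussian initialization for a chain of dense layers.
init_sae <- function(cfg) {
  sizes <- cfg$layer_sizes
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
      sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  structure(list(cfg = cfg, params = params, trained = FALSE,
                 loss_trace = numeric(0)),
            class = "sae_model")
}

# Forward pass caching pre-activations and activations per layer.
sae_forward <- function(model, X) {
  sizes <- model$cfg$layer_sizes
  n_layers <- length(sizes)
  A <- vector("list", n_layers)
  Z <- vector("list", n_layers)
  A[[1L]] <- X
  for (l in seq_len(n_layers - 1L)) {
    Z[[l + 1L]] <- add_bias_rows(A[[l]] %*% model$params[[paste0("W", l)]],
                                 model$params[[paste0("b", l)]])
    A[[l + 1L]] <- if (l + 1L < n_layers) relu(Z[[l + 1L]]) else Z[[l + 1L]]
  }
  list(A = A, Z = Z)
}

#' Bernoulli Kullback-Leibler sparsity penalty
#'
#' `KL(p || p_hat) = p log(p / p_hat) + (1 - p) log((1 - p) / (1 - p_hat))`,
#' the divergence between Bernoulli means. `p_hat` is clipped to
#' `[1e-8, 1 - 1e-8]` before evaluation so ReLU activations (which are
#' unbounded above) cannot produce infinities.
#'
#' @param p Sparsity target in (0, 1).
#' @param p_hat Observed mean activation(s); vectorized.
#' @return Non-negative divergence value(s); zero iff `p_hat == p`.
#' @export
kl_sparsity <- function(p, p_hat) {
  if (length(p) != 1L || !is.numeric(p) || is.na(p) || p <= 0 || p >= 1) {
    abort_arg("`p` must be a single number strictly inside (0, 1)")
  }
  q <- pmin(pmax(p_hat, 1e-8), 1 - 1e-8)
  p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
}

#' Sparse autoencoder cost and analytic gradient
#'
#' Mean over the batch of half squared reconstruction error, plus
#' `lambda/2 * sum(W^2)` over every weight matrix, plus `beta` times the
#' summed KL penalty between the target `p` and each bottleneck unit's mean
#' activation over the batch.
#'
#' @param model An `sae_model`.
#' @param batch Numeric matrix, one sample per row; width must equal the
#'   input layer size.
#' @param cfg Optional `sae_config` overriding the model's config.
#' @return List with `cost`, the `components` (reconstruction / decay /
#'   sparsity), per-unit `p_hat`, and `grads` (named like `model$params`).
#' @export
sae_cost <- function(model, batch, cfg = model$cfg) {
  if (!inherits(model, "sae_model")) abort_arg("`model` must be an sae_model")
  batch <- as.matrix(batch)
  if (ncol(batch) != cfg$layer_sizes[1L]) {
    abort_arg(sprintf("batch width %d != input layer size %d",
                      ncol(batch), cfg$layer_sizes[1L]))
  }
  n <- nrow(batch)
  n_layers <- length(cfg$layer_sizes)
  fw <- sae_forward(model, batch)
  A <- fw$A; Z <- fw$Z
  recon_err <- A[[n_layers]] - batch
  recon <- sum(recon_err^2) / (2 * n)
  decay_sum <- 0
  for (l in seq_len(n_layers - 1L)) {
    decay_sum <- decay_sum + sum(model$params[[paste0("W", l)]]^2)
  }
  decay <- cfg$weight_decay / 2 * decay_sum
  bi <- cfg$bottleneck
  p_hat <- colMeans(A[[bi]])
  p <- cfg$sparsity_target
  sparsity <- cfg$sparse_penalty * sum(kl_sparsity(p, p_hat))

  grads <- lapply(model$params, function(x) array(0, dim = dim(x) %||% length(x)))
  dZ <- recon_err / n
  for (l in rev(seq_len(n_layers - 1L))) {
    grads[[paste0("W", l)]] <- t(A[[l]]) %*% dZ +
      cfg$weight_decay * model$params[[paste0("W", l)]]
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(model$params[[paste0("W", l)]])
      if (l == bi) {
        q <- pmin(pmax(p_hat, 1e-8), 1 - 1e-8)
        dkl <- ifelse(p_hat > 1e-8 & p_hat < 1 - 1e-8,
                      -p / q + (1 - p) / (1 - q), 0)
        dA <- sweep(dA, 2L, cfg$sparse_penalty * dkl / n, "+")
      }
      dZ <- dA * (Z[[l]] > 0)
    }
  }
  list(cost = recon + decay + sparsity,
       components = c(reconstruction = recon, decay = decay, sparsity = sparsity),
       p_hat = p_hat, grads = grads)
}

#' Train a sparse autoencoder
#'
#' Adam over mini-batches for `cfg$iterations` epochs; the full-data cost is
#' recorded per epoch in `loss_trace`. Deterministic under `cfg$seed`.
#'
#' @param data An `eeg_segment_set` or a numeric matrix (rows = samples).
#' @param cfg An [sae_config()].
#' @return A trained `sae_model`.
#' @export
train_sae <- function(data, cfg) {
  if (!inherits(cfg, "sae_config")) abort_arg("`cfg` must be an sae_config")
  X <- if (inherits(data, "eeg_segment_set")) segments_as_matrix(data) else as.matrix(data)
  if (nrow(X) < 1L) abort_arg("`data` must contain at least one sample")
  if (ncol(X) != cfg$layer_sizes[1L]) {
    abort_arg(sprintf("data width %d != input layer size %d",
                      ncol(X), cfg$layer_sizes[1L]))
  }
  with_seed(cfg$seed, {
    model <- init_sae(cfg)
    opt <- adam_init(model$params)
    n <- nrow(X)
    bs <- min(cfg$batch_size, n)
    trace <- numeric(cfg$iterations)
    for (epoch in seq_len(cfg$iterations)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        take <- idx[start:min(start + bs - 1L, n)]
        cg <- sae_cost(model, X[take, , drop = FALSE], cfg)
        if (!is.finite(cg$cost)) {
          abort_training(sprintf("non-finite loss at epoch %d", epoch))
        }
        step <- adam_step(model$params, cg$grads, opt, cfg$learning_rate)
        model$params <- step$params
        opt <- step$state
      }
      trace[epoch] <- sae_cost(model, X, cfg)$cost
      if (!is.finite(trace[epoch])) {
        abort_training(sprintf("non-finite loss at epoch %d", epoch))
      }
    }
    model$loss_trace <- trace
    model$trained <- TRUE
    model
  })
}

#' Encode data to bottleneck features
#'
#' @param model A trained `sae_model`.
#' @param data An `eeg_segment_set` or numeric matrix.
#' @return `n x bottleneck_size` matrix of ReLU bottleneck activations.
#' @export
encode <- function(model, data) {
  if (!inherits(model, "sae_model")) abort_state("`model` must be an sae_model")
  if (!isTRUE(model$trained)) abort_state("model has not been trained")
  X <- if (inherits(data, "eeg_segment_set")) segments_as_matrix(data) else as.matrix(data)
  if (ncol(X) != model$cfg$layer_sizes[1L]) {
    abort_state(sprintf("data width %d != model input size %d",
                        ncol(X), model$cfg$layer_sizes[1L]))
  }
  fw <- sae_forward(model, X)
  fw$A[[model$cfg$bottleneck]]
}

#' Mean bottleneck activation per unit
#'
#' @param model A trained `sae_model`.
#' @param data Samples to measure over.
#' @return List with `p_hat` (per-unit means) and `n_samples`.
#' @export
sparsity_stats <- function(model, data) {
  feats <- encode(model, data)
  list(p_hat = colMeans(feats), n_samples = nrow(feats))
}
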