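# Internal numerics, error classes and optimizer kernels shared by all modules.

abort_arg <- function(msg) {
  stop(errorCondition(msg, class = c("eegdeep_argument_error", "eegdeep_error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("eegdeep_format_error", "eegdeep_error")))
}

abort_state <- function(msg) {
  stop(errorCondition(msg, class = c("eegdeep_state_error", "eegdeep_error")))
}

abort_training <- function(msg) {
  stop(errorCondition(msg, class = c("eegdeep_training_error", "eegdeep_error")))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper) {
    abort_arg(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  as.numeric(x)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards so
# seeded package functions never perturb the user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(x) {
  x <- as.matrix(x)
  shifted <- x - apply(x, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

one_hot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  out <- matrix(0, nrow = length(labels), ncol = n_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

cross_entropy <- function(prob, labels) {
  p <- prob[cbind(seq_along(labels), as.integer(labels) + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# Per-row z-score; rows with zero variance are centred only.
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  centred <- x - mu
  s <- sqrt(rowMeans(centred^2))
  s[s < 1e-12] <- 1
  centred / s
}

add_bias_rows <- function(x, b) {
  # x: n x d, b: length-d bias applied to every row
  sweep(x, 2L, b, "+")
}

## ---- optimizer kernels over named lists of parameter arrays ----------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

rmsprop_init <- function(params) {
  list(v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# Max-norm constraint: rescale rows of each weight matrix whose L2 norm
# exceeds `max_norm` (incoming-weight norm per unit).
apply_max_norm <- function(params, max_norm, which_names = names(params)) {
  if (!is.finite(max_norm) || max_norm <= 0) return(params)
  for (nm in which_names) {
    w <- params[[nm]]
    if (is.matrix(w)) {
      norms <- sqrt(rowSums(w^2))
      scale <- pmin(1, max_norm / pmax(norms, 1e-12))
      params[[nm]] <- w * scale
    }
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k) * 7919) %% 2147483647L)
}
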