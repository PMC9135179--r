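# Shared fixtures and oracles, all built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct discrete-Fourier periodogram band power (independent oracle for the
# generator's spectral claims).
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(sp[freqs >= lo & freqs <= hi])
}

# Central-difference gradient oracle over a named list of parameter arrays.
num_grad <- function(fn, params, eps = 1e-6) {
  g <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g[[nm]][i] <- (fn(pp) - fn(pm)) / (2 * eps)
    }
  }
  g
}

grad_rel_err <- function(a, b) {
  va <- unlist(a); vb <- unlist(b)
  sqrt(sum((va - vb)^2)) / max(sqrt(sum(va^2)), sqrt(sum(vb^2)), 1e-12)
}

# Small pooled two-class segment set used across module tests.
small_pool <- function(n_per_class = 6L, seed = 3L) {
  recs <- generate_bonn_like(n_per_class, 4097L, seed = seed)
  pool_segment_sets(lapply(recs, segment_recording, n_chunks = 23L))
}

# Synthetic wrapper-selection problem: 8 weakly informative columns
# (effect size 0.8) among 40.
make_recovery_problem <- function(seed, n = 240L, d = 40L, n_info = 8L,
                                  effect = 0.8) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(stats::rnorm(n * d), n, d)
  X[, seq_len(n_info)] <- X[, seq_len(n_info)] + effect * (2 * y - 1)
  list(X = X, y = y, info = seq_len(n_info))
}

# Two-stage toy decision MDP with known rewards, plus a value-iteration
# oracle over its three states (1 = s1, 2 = s2, 3 = terminal).
toy_mdp <- function() {
  # action rewards: a1 commits (terminal, r = 0.2); a2 defers (r = 0.1 -> s2);
  # a3 terminal r = 1; a4 terminal r = -1. Optimal: defer then a3 (value 1.1).
  list(
    step = function(s, a) {
      if (s == 1L && a == 1L) list(r = 0.2, s_next = 3L)
      else if (s == 1L && a == 2L) list(r = 0.1, s_next = 2L)
      else if (s == 2L && a == 3L) list(r = 1, s_next = 3L)
      else if (s == 2L && a == 4L) list(r = -1, s_next = 3L)
      else stop("illegal action")
    },
    legal = list(`1` = c(1L, 2L), `2` = c(3L, 4L))
  )
}

value_iteration_oracle <- function(mdp, n_iter = 100L) {
  Q <- matrix(0, 3L, 4L)
  for (it in seq_len(n_iter)) {
    for (s in 1:2) for (a in mdp$legal[[as.character(s)]]) {
      tr <- mdp$step(s, a)
      boot <- if (tr$s_next == 3L) 0 else {
        max(Q[tr$s_next, mdp$legal[[as.character(tr$s_next)]]])
      }
      Q[s, a] <- tr$r + boot
    }
  }
  Q
}

# Tiny RBATQ state-builder parameter sets for episode-level tests.
tiny_builders <- function(seed = 5L, f_dim = 4L, state = 3L, hidden = 4L) {
  eegdeep:::with_seed(seed, {
    list(theta_rnn = eegdeep:::init_bilstm_params(f_dim, state, hidden, 2L),
         theta_tree = eegdeep:::init_tree_params(2L * f_dim, state, 2L),
         cfg = rbatq_config(state_size = state, hidden = hidden, n_frames = 4L,
                            tree_depth = 1L, dropout_rate = 0,
                            pretrain_epochs = 1L, epochs = 1L, seed = seed))
  })
}
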