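# Reinforcement-learning classifier: a peephole BiLSTM with additive
# attention builds the initial decision state s1, a child-sum Tree-LSTM over
# contiguous sub-windows builds the transition state s2, and a Q-network
# trained with a visit-count running-average target decides per signal whether
# to commit to the recurrent head's prediction (a1) or defer to the tree state
# (a2) and then predict class 0 (a3) or class 1 (a4). Episodes end in the
# terminal state s_e after at most two decisions.

#' RBATQ configuration
#'
#' Defaults follow the published operating point: LSTM state size 250 for all
#' LSTM units, hidden dimension 100 (attention scorer and Q-network), tanh
#' non-linearity, dropout rate 0.75, learning rate 0.002, mini-batch 25 and a
#' max-norm constraint of 3. Terminal rewards are +1/-1 for
#' correct/incorrect predictions and deferral earns a small positive reward.
#'
#' @param state_size LSTM state size (both BiLSTM directions and Tree-LSTM).
#' @param hidden Hidden dimension of the attention scorer and Q-network.
#' @param n_frames Number of contiguous frames a segment is split into before
#'   entering the recurrent networks (the LSTM sequence length).
#' @param tree_depth Depth of the balanced binary tree over contiguous frame
#'   chunks (`2^tree_depth` leaves; 0 gives a single leaf).
#' @param dropout_rate Drop probability applied to pooled states during
#'   pre-training.
#' @param learning_rate RMSprop step size (pre-training and Q-learning).
#' @param batch_size Pre-training mini-batch size.
#' @param max_norm Max-norm constraint on state-builder weight rows.
#' @param pretrain_epochs Supervised pre-training epochs for both state
#'   builders.
#' @param epochs Q-learning epochs (sweeps over all signals).
#' @param eps_start,eps_end Epsilon-greedy exploration rate, decayed linearly
#'   across epochs.
#' @param r_defer Reward for the defer action a2.
#' @param seed Integer seed.
#' @return A list of class `rbatq_config`.
#' @export
rbatq_config <- function(state_size = 250L, hidden = 100L, n_frames = 8L,
                         tree_depth = 2L, dropout_rate = 0.75,
                         learning_rate = 0.002, batch_size = 25L,
                         max_norm = 3, pretrain_epochs = 20L, epochs = 20L,
                         eps_start = 0.5, eps_end = 0.05, r_defer = 0.1,
                         seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) abort_arg("`dropout_rate` must be in [0, 1)")
  tree_depth <- check_count(tree_depth, "tree_depth", min = 0L)
  n_frames <- check_count(n_frames, "n_frames")
  if (n_frames < 2^tree_depth) abort_arg("`n_frames` must cover at least one frame per leaf")
  structure(list(state_size = check_count(state_size, "state_size"),
                 hidden = check_count(hidden, "hidden"),
                 n_frames = n_frames, tree_depth = tree_depth,
                 dropout_rate = as.numeric(dropout_rate),
                 learning_rate = check_scalar(learning_rate, "learning_rate", lower = 1e-12),
                 batch_size = check_count(batch_size, "batch_size"),
                 max_norm = check_scalar(max_norm, "max_norm", lower = 0),
                 pretrain_epochs = check_count(pretrain_epochs, "pretrain_epochs"),
                 epochs = check_count(epochs, "epochs"),
                 eps_start = check_scalar(eps_start, "eps_start", lower = 0, upper = 1),
                 eps_end = check_scalar(eps_end, "eps_end", lower = 0, upper = 1),
                 r_defer = check_scalar(r_defer, "r_defer"),
                 n_classes = 2L,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "rbatq_config")
}

#' The two-stage decision process of the agent
#'
#' States: initial `s1` (attention-pooled BiLSTM), transition `s2`
#' (Tree-LSTM root), terminal `s_e`. Actions: `a1` commit to the recurrent
#' head's prediction, `a2` defer to the tree state, `a3`/`a4` predict class
#' 0/1. Every episode terminates in `s_e` within two decisions.
#'
#' @param r_correct,r_incorrect,r_defer Reward values.
#' @return A list describing states, actions, rewards and legal transitions.
#' @export
decision_mdp <- function(r_correct = 1, r_incorrect = -1, r_defer = 0.1) {
  list(states = c("s1", "s2", "s_e"),
       actions = c(a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L),
       legal = list(s1 = c(1L, 2L), s2 = c(3L, 4L)),
       rewards = c(r_correct = r_correct, r_incorrect = r_incorrect,
                   r_defer = r_defer),
       transitions = list(c("s1", "a1", "r1", "s_e"),
                          c("s1", "a2", "r2", "s2"),
                          c("s2", "a3", "r3", "s_e"),
                          c("s2", "a4", "r4", "s_e")))
}

## ---- framing ---------------------------------------------------------------

# Split each row of X (n x L) into n_frames contiguous frames; returns an
# n x n_frames x frame_len array (the trailing remainder is dropped).
frame_matrix <- function(X, n_frames) {
  L <- ncol(X)
  f <- L %/% n_frames
  if (f < 1L) abort_arg("segments are shorter than the number of frames")
  out <- array(0, dim = c(nrow(X), n_frames, f))
  for (t in seq_len(n_frames)) {
    out[, t, ] <- X[, (t - 1L) * f + seq_len(f), drop = FALSE]
  }
  out
}

# Frames for a segment set: multichannel data contributes all channels to
# each time frame (frame width = frame_len * n_channels).
frame_segment_set <- function(set, n_frames) {
  if (inherits(set, "eeg_segment_set") && set$channel_count > 1L) {
    per_ch <- lapply(seq_len(set$channel_count), function(ch) {
      frame_matrix(set$segments[, , ch], n_frames)
    })
    f <- dim(per_ch[[1L]])[3L]
    n <- dim(per_ch[[1L]])[1L]
    out <- array(0, dim = c(n, n_frames, f * set$channel_count))
    for (ch in seq_along(per_ch)) {
      out[, , (ch - 1L) * f + seq_len(f)] <- per_ch[[ch]]
    }
    return(out)
  }
  X <- if (inherits(set, "eeg_segment_set")) set$segments else as.matrix(set)
  frame_matrix(X, n_frames)
}

## ---- parameter initialization ---------------------------------------------

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
}

init_bilstm_params <- function(input_dim, state_size, hidden, n_classes) {
  p <- list()
  for (dir in c("f", "b")) {
    for (gate in c("i", "f", "c", "o")) {
      p[[paste0(dir, "_Wx", gate)]] <- glorot(input_dim, state_size) * 0.5
      p[[paste0(dir, "_Wh", gate)]] <- glorot(state_size, state_size) * 0.5
      p[[paste0(dir, "_Wc", gate)]] <- glorot(state_size, state_size) * 0.5
      p[[paste0(dir, "_b", gate)]] <- if (gate == "f") rep(1, state_size) else numeric(state_size)
    }
  }
  p$Why <- glorot(state_size, n_classes)
  p$Wpy <- glorot(state_size, n_classes)
  p$by <- numeric(n_classes)
  p$Wa <- glorot(2L * state_size, hidden)
  p$va <- stats::rnorm(hidden, sd = sqrt(1 / hidden))
  p
}

init_tree_params <- function(leaf_dim, state_size, n_classes) {
  p <- list()
  for (gate in c("i", "u", "o")) {
    p[[paste0("W", gate)]] <- glorot(leaf_dim, state_size) * 0.5
    p[[paste0("U", gate)]] <- glorot(state_size, state_size) * 0.5
    p[[paste0("b", gate)]] <- numeric(state_size)
  }
  p$Uf <- glorot(state_size, state_size) * 0.5
  p$bf <- rep(1, state_size)
  p$Wsy <- glorot(state_size, n_classes)
  p$bry <- numeric(n_classes)
  p
}

## ---- BiLSTM forward / backward --------------------------------------------

# One direction over a batch. X3: n x T x f. Returns H (n x T x s) and the
# per-step cache needed for BPTT.
lstm_dir_forward <- function(X3, p, dir) {
  n <- dim(X3)[1L]; T_ <- dim(X3)[2L]
  s <- ncol(p[[paste0(dir, "_Whi")]])
  H <- array(0, dim = c(n, T_, s))
  h <- matrix(0, n, s); c_ <- matrix(0, n, s)
  cache <- vector("list", T_)
  g <- function(nm) p[[paste0(dir, "_", nm)]]
  for (t in seq_len(T_)) {
    Xt <- matrix(X3[, t, ], n)
    h_prev <- h; c_prev <- c_
    I <- sigmoid(add_bias_rows(Xt %*% g("Wxi") + h_prev %*% g("Whi") +
                                 c_prev %*% g("Wci"), g("bi")))
    F_ <- sigmoid(add_bias_rows(Xt %*% g("Wxf") + h_prev %*% g("Whf") +
                                  c_prev %*% g("Wcf"), g("bf")))
    G <- tanh(add_bias_rows(Xt %*% g("Wxc") + h_prev %*% g("Whc") +
                              c_prev %*% g("Wcc"), g("bc")))
    c_ <- I * G + F_ * c_prev
    O <- sigmoid(add_bias_rows(Xt %*% g("Wxo") + h_prev %*% g("Who") +
                                 c_ %*% g("Wco"), g("bo")))
    tc <- tanh(c_)
    h <- O * tc
    H[, t, ] <- h
    cache[[t]] <- list(Xt = Xt, I = I, F = F_, G = G, O = O, C = c_,
                       tanhC = tc, h_prev = h_prev, c_prev = c_prev)
  }
  list(H = H, cache = cache)
}

# BPTT for one direction. dH_ext: n x T x s external gradient on H.
lstm_dir_backward <- function(dH_ext, cache, p, dir, grads) {
  T_ <- length(cache)
  s <- ncol(p[[paste0(dir, "_Whi")]])
  n <- nrow(cache[[1L]]$Xt)
  g <- function(nm) p[[paste0(dir, "_", nm)]]
  nm <- function(x) paste0(dir, "_", x)
  dh_carry <- matrix(0, n, s); dc_carry <- matrix(0, n, s)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dH <- matrix(dH_ext[, t, ], n) + dh_carry
    dPre_o <- dH * cc$tanhC * cc$O * (1 - cc$O)
    dC <- dH * cc$O * (1 - cc$tanhC^2) + dc_carry + dPre_o %*% t(g("Wco"))
    dI <- dC * cc$G
    dG <- dC * cc$I
    dF <- dC * cc$c_prev
    dPre_i <- dI * cc$I * (1 - cc$I)
    dPre_f <- dF * cc$F * (1 - cc$F)
    dPre_g <- dG * (1 - cc$G^2)
    grads[[nm("Wxi")]] <- grads[[nm("Wxi")]] + t(cc$Xt) %*% dPre_i
    grads[[nm("Whi")]] <- grads[[nm("Whi")]] + t(cc$h_prev) %*% dPre_i
    grads[[nm("Wci")]] <- grads[[nm("Wci")]] + t(cc$c_prev) %*% dPre_i
    grads[[nm("bi")]] <- grads[[nm("bi")]] + colSums(dPre_i)
    grads[[nm("Wxf")]] <- grads[[nm("Wxf")]] + t(cc$Xt) %*% dPre_f
    grads[[nm("Whf")]] <- grads[[nm("Whf")]] + t(cc$h_prev) %*% dPre_f
    grads[[nm("Wcf")]] <- grads[[nm("Wcf")]] + t(cc$c_prev) %*% dPre_f
    grads[[nm("bf")]] <- grads[[nm("bf")]] + colSums(dPre_f)
    grads[[nm("Wxc")]] <- grads[[nm("Wxc")]] + t(cc$Xt) %*% dPre_g
    grads[[nm("Whc")]] <- grads[[nm("Whc")]] + t(cc$h_prev) %*% dPre_g
    grads[[nm("Wcc")]] <- grads[[nm("Wcc")]] + t(cc$c_prev) %*% dPre_g
    grads[[nm("bc")]] <- grads[[nm("bc")]] + colSums(dPre_g)
    grads[[nm("Wxo")]] <- grads[[nm("Wxo")]] + t(cc$Xt) %*% dPre_o
    grads[[nm("Who")]] <- grads[[nm("Who")]] + t(cc$h_prev) %*% dPre_o
    grads[[nm("Wco")]] <- grads[[nm("Wco")]] + t(cc$C) %*% dPre_o
    grads[[nm("bo")]] <- grads[[nm("bo")]] + colSums(dPre_o)
    dh_carry <- dPre_i %*% t(g("Whi")) + dPre_f %*% t(g("Whf")) +
      dPre_g %*% t(g("Whc")) + dPre_o %*% t(g("Who"))
    dc_carry <- dC * cc$F + dPre_i %*% t(g("Wci")) + dPre_f %*% t(g("Wcf")) +
      dPre_g %*% t(g("Wcc"))
  }
  grads
}

# Bidirectional forward over a batch: backward direction runs on
# time-reversed input, and its states are re-aligned to original time.
bilstm_batch_forward <- function(X3, p) {
  fw <- lstm_dir_forward(X3, p, "f")
  T_ <- dim(X3)[2L]
  Xrev <- X3[, rev(seq_len(T_)), , drop = FALSE]
  bw <- lstm_dir_forward(Xrev, p, "b")
  Hp <- bw$H[, rev(seq_len(T_)), , drop = FALSE]
  list(H = fw$H, Hp = Hp, cache_f = fw$cache, cache_b = bw$cache)
}

#' BiLSTM forward pass over one sequence
#'
#' Gates follow the peephole formulation: the input and forget gates see the
#' previous cell state and the output gate sees the current one. The backward
#' direction mirrors time. Each time step's forward and backward states feed
#' a softmax head `y_t = softmax(Why h_t + Wpy h'_t + by)`.
#'
#' @param x_seq Numeric matrix `T x f` of per-frame feature vectors.
#' @param params BiLSTM parameter list (see `init_bilstm_params`).
#' @return List with `h_seq`, `hp_seq` (`T x state_size`) and row-stochastic
#'   `y_seq` (`T x n_classes`).
#' @export
bilstm_forward <- function(x_seq, params) {
  x_seq <- as.matrix(x_seq)
  if (nrow(x_seq) < 1L) abort_arg("`x_seq` must have at least one time step")
  if (ncol(x_seq) != nrow(params$f_Wxi)) {
    abort_arg(sprintf("frame width %d != parameter input width %d",
                      ncol(x_seq), nrow(params$f_Wxi)))
  }
  X3 <- array(0, dim = c(1L, nrow(x_seq), ncol(x_seq)))
  X3[1L, , ] <- x_seq
  fw <- bilstm_batch_forward(X3, params)
  T_ <- nrow(x_seq)
  s <- dim(fw$H)[3L]
  h_seq <- matrix(fw$H[1L, , ], T_, s)
  hp_seq <- matrix(fw$Hp[1L, , ], T_, s)
  logits <- add_bias_rows(h_seq %*% params$Why + hp_seq %*% params$Wpy,
                          params$by)
  list(h_seq = h_seq, hp_seq = hp_seq, y_seq = softmax_rows(logits))
}

## ---- attention -------------------------------------------------------------

# Batched additive attention over time. H/Hp: n x T x s. Returns pooled state
# S1 (n x 2s), weights A (n x T) and the cache for backprop.
att_batch_forward <- function(H, Hp, p) {
  n <- dim(H)[1L]; T_ <- dim(H)[2L]; s <- dim(H)[3L]
  scores <- matrix(0, n, T_)
  M <- vector("list", T_)
  U <- vector("list", T_)
  for (t in seq_len(T_)) {
    U[[t]] <- cbind(matrix(H[, t, ], n), matrix(Hp[, t, ], n))
    M[[t]] <- tanh(U[[t]] %*% p$Wa)
    scores[, t] <- M[[t]] %*% p$va
  }
  A <- softmax_rows(scores)
  S1 <- matrix(0, n, 2L * s)
  for (t in seq_len(T_)) S1 <- S1 + A[, t] * U[[t]]
  list(S1 = S1, A = A, M = M, U = U)
}

# Backprop through attention pooling; returns dH/dHp arrays and accumulates
# attention-parameter gradients.
att_batch_backward <- function(dS1, att, p, grads) {
  T_ <- ncol(att$A)
  n <- nrow(dS1)
  s2 <- ncol(dS1)
  da <- matrix(0, n, T_)
  dU <- vector("list", T_)
  for (t in seq_len(T_)) {
    da[, t] <- rowSums(dS1 * att$U[[t]])
    dU[[t]] <- att$A[, t] * dS1
  }
  dscore <- att$A * (da - rowSums(att$A * da))
  for (t in seq_len(T_)) {
    grads$va <- grads$va + colSums(att$M[[t]] * dscore[, t])
    dM <- outer(dscore[, t], p$va)
    dPre <- dM * (1 - att$M[[t]]^2)
    grads$Wa <- grads$Wa + t(att$U[[t]]) %*% dPre
    dU[[t]] <- dU[[t]] + dPre %*% t(p$Wa)
  }
  s <- s2 %/% 2L
  dH <- array(0, dim = c(n, T_, s))
  dHp <- array(0, dim = c(n, T_, s))
  for (t in seq_len(T_)) {
    dH[, t, ] <- dU[[t]][, seq_len(s), drop = FALSE]
    dHp[, t, ] <- dU[[t]][, s + seq_len(s), drop = FALSE]
  }
  list(dH = dH, dHp = dHp, grads = grads)
}

#' Attention-pooled initial state
#'
#' `s1 = sum_t a_t [h_t; h'_t]` with additive scores
#' `a = softmax_t(va . tanh(Wa [h_t; h'_t]))`; the weights are non-negative
#' and sum to one.
#'
#' @param h_seq,hp_seq `T x state_size` forward/backward state matrices.
#' @param params Parameter list holding `Wa` and `va`.
#' @return List with the pooled vector `s1` and the attention `weights`.
#' @export
attention_state <- function(h_seq, hp_seq, params) {
  h_seq <- as.matrix(h_seq); hp_seq <- as.matrix(hp_seq)
  if (nrow(h_seq) < 1L) abort_arg("empty sequence")
  if (!identical(dim(h_seq), dim(hp_seq))) abort_arg("state sequences disagree in shape")
  T_ <- nrow(h_seq); s <- ncol(h_seq)
  H <- array(0, dim = c(1L, T_, s)); H[1L, , ] <- h_seq
  Hp <- array(0, dim = c(1L, T_, s)); Hp[1L, , ] <- hp_seq
  att <- att_batch_forward(H, Hp, params)
  list(s1 = as.numeric(att$S1[1L, ]), weights = as.numeric(att$A[1L, ]))
}

# Supervised pre-training loss for the BiLSTM + attention stage: the per-step
# softmax head applied to the attention-pooled state (equivalently the
# attention-weighted average of per-step logits), cross-entropy against the
# labels. Returns cost and full analytic gradients.
bilstm_att_loss <- function(p, X3, y, n_classes, drop_mask = NULL) {
  n <- dim(X3)[1L]
  fw <- bilstm_batch_forward(X3, p)
  att <- att_batch_forward(fw$H, fw$Hp, p)
  S1 <- att$S1
  if (!is.null(drop_mask)) S1 <- S1 * drop_mask
  s <- dim(fw$H)[3L]
  S1h <- S1[, seq_len(s), drop = FALSE]
  S1p <- S1[, s + seq_len(s), drop = FALSE]
  logits <- add_bias_rows(S1h %*% p$Why + S1p %*% p$Wpy, p$by)
  prob <- softmax_rows(logits)
  cost <- cross_entropy(prob, y)
  grads <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  dlog <- (prob - one_hot(y, n_classes)) / n
  grads$Why <- t(S1h) %*% dlog
  grads$Wpy <- t(S1p) %*% dlog
  grads$by <- colSums(dlog)
  dS1 <- cbind(dlog %*% t(p$Why), dlog %*% t(p$Wpy))
  if (!is.null(drop_mask)) dS1 <- dS1 * drop_mask
  ab <- att_batch_backward(dS1, att, p, grads)
  grads <- ab$grads
  grads <- lstm_dir_backward(ab$dH, fw$cache_f, p, "f", grads)
  T_ <- dim(X3)[2L]
  dHp_rev <- ab$dHp[, rev(seq_len(T_)), , drop = FALSE]
  grads <- lstm_dir_backward(dHp_rev, fw$cache_b, p, "b", grads)
  list(cost = cost, grads = grads, prob = prob, S1 = att$S1)
}

## ---- Tree-LSTM -------------------------------------------------------------

# Balanced binary tree over 2^depth contiguous chunks of the frame sequence.
# Leaves embed their chunk (flattened) through the input maps; internal nodes
# combine children by child-sum composition with one forget gate per child.
tree_leaf_inputs <- function(X3, depth) {
  n <- dim(X3)[1L]; T_ <- dim(X3)[2L]; f <- dim(X3)[3L]
  n_leaves <- 2L^depth
  per <- T_ %/% n_leaves
  if (per < 1L) abort_arg("too few frames for the tree depth")
  lapply(seq_len(n_leaves), function(l) {
    idx <- (l - 1L) * per + seq_len(per)
    matrix(X3[, idx, , drop = FALSE], n, per * f)
  })
}

tree_node_forward <- function(p, x = NULL, children = list()) {
  n <- if (!is.null(x)) nrow(x) else nrow(children[[1L]]$h)
  s <- ncol(p$Ui)
  hsum <- matrix(0, n, s)
  for (ch in children) hsum <- hsum + ch$h
  lin <- function(gate) {
    pre <- hsum %*% p[[paste0("U", gate)]]
    if (!is.null(x)) pre <- pre + x %*% p[[paste0("W", gate)]]
    add_bias_rows(pre, p[[paste0("b", gate)]])
  }
  I <- sigmoid(lin("i"))
  Uv <- tanh(lin("u"))
  O <- sigmoid(lin("o"))
  C <- I * Uv
  Fg <- vector("list", length(children))
  for (k in seq_along(children)) {
    Fg[[k]] <- sigmoid(add_bias_rows(children[[k]]$h %*% p$Uf, p$bf))
    C <- C + Fg[[k]] * children[[k]]$c
  }
  tc <- tanh(C)
  list(h = O * tc, c = C, I = I, Uv = Uv, O = O, tanhC = tc, Fg = Fg,
       hsum = hsum, x = x, children = children)
}

# Backward through one node; returns gradients and the (dh, dc) to pass to
# each child.
tree_node_backward <- function(node, dh, dc, p, grads) {
  dPre_o <- dh * node$tanhC * node$O * (1 - node$O)
  dC <- dh * node$O * (1 - node$tanhC^2) + dc
  dI <- dC * node$Uv
  dUv <- dC * node$I
  dPre_i <- dI * node$I * (1 - node$I)
  dPre_u <- dUv * (1 - node$Uv^2)
  if (!is.null(node$x)) {
    grads$Wi <- grads$Wi + t(node$x) %*% dPre_i
    grads$Wu <- grads$Wu + t(node$x) %*% dPre_u
    grads$Wo <- grads$Wo + t(node$x) %*% dPre_o
  }
  grads$Ui <- grads$Ui + t(node$hsum) %*% dPre_i
  grads$Uu <- grads$Uu + t(node$hsum) %*% dPre_u
  grads$Uo <- grads$Uo + t(node$hsum) %*% dPre_o
  grads$bi <- grads$bi + colSums(dPre_i)
  grads$bu <- grads$bu + colSums(dPre_u)
  grads$bo <- grads$bo + colSums(dPre_o)
  dhsum <- dPre_i %*% t(p$Ui) + dPre_u %*% t(p$Uu) + dPre_o %*% t(p$Uo)
  child_grads <- vector("list", length(node$children))
  for (k in seq_along(node$children)) {
    ch <- node$children[[k]]
    dF <- dC * ch$c
    dPre_f <- dF * node$Fg[[k]] * (1 - node$Fg[[k]])
    grads$Uf <- grads$Uf + t(ch$h) %*% dPre_f
    grads$bf <- grads$bf + colSums(dPre_f)
    child_grads[[k]] <- list(dh = dhsum + dPre_f %*% t(p$Uf),
                             dc = dC * node$Fg[[k]])
  }
  list(grads = grads, child_grads = child_grads)
}

# Full tree forward over a batch; returns the root state, head output and the
# node cache (leaves first, then successive levels up to the root).
tree_batch_forward <- function(X3, p, depth) {
  leaves_x <- tree_leaf_inputs(X3, depth)
  level <- lapply(leaves_x, function(x) tree_node_forward(p, x = x))
  levels <- list(level)
  while (length(level) > 1L) {
    level <- lapply(seq_len(length(level) %/% 2L), function(j) {
      tree_node_forward(p, children = level[(2L * j - 1L):(2L * j)])
    })
    levels[[length(levels) + 1L]] <- level
  }
  root <- level[[1L]]
  logits <- add_bias_rows(root$h %*% p$Wsy, p$bry)
  list(S2 = root$h, y_r = softmax_rows(logits), levels = levels)
}

tree_loss <- function(p, X3, y, n_classes, depth, drop_mask = NULL) {
  fw <- tree_batch_forward(X3, p, depth)
  n <- nrow(fw$S2)
  S2 <- fw$S2
  if (!is.null(drop_mask)) S2 <- S2 * drop_mask
  logits <- add_bias_rows(S2 %*% p$Wsy, p$bry)
  prob <- softmax_rows(logits)
  cost <- cross_entropy(prob, y)
  grads <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  dlog <- (prob - one_hot(y, n_classes)) / n
  grads$Wsy <- t(S2) %*% dlog
  grads$bry <- colSums(dlog)
  dh_root <- dlog %*% t(p$Wsy)
  if (!is.null(drop_mask)) dh_root <- dh_root * drop_mask
  # walk levels top-down, carrying (dh, dc) per node
  n_levels <- length(fw$levels)
  zero <- matrix(0, n, ncol(fw$S2))
  carry <- list(list(dh = dh_root, dc = zero))
  for (lev in rev(seq_len(n_levels))) {
    nodes <- fw$levels[[lev]]
    next_carry <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      bk <- tree_node_backward(nodes[[j]], carry[[j]]$dh, carry[[j]]$dc, p, grads)
      grads <- bk$grads
      if (length(bk$child_grads) > 0L) {
        next_carry[[2L * j - 1L]] <- bk$child_grads[[1L]]
        next_carry[[2L * j]] <- bk$child_grads[[2L]]
      }
    }
    carry <- next_carry
  }
  list(cost = cost, grads = grads, prob = prob, S2 = fw$S2)
}

#' Tree-LSTM transition state for one sequence
#'
#' The frame sequence is split into `2^depth` contiguous chunks; each chunk is
#' a leaf, and internal nodes combine their two children by child-sum
#' composition (children's hidden states summed into the gate inputs, one
#' forget gate per child) up to the root. `s2` is the root hidden state and
#' `y_r = softmax(Wsy s2 + bry)`.
#'
#' @param x_seq Numeric matrix `T x f` of per-frame feature vectors.
#' @param params Tree-LSTM parameter list (see `init_tree_params`).
#' @param depth Tree depth (0 = single leaf).
#' @return List with `s2` (root state vector) and probability vector `y_r`.
#' @export
tree_state <- function(x_seq, params, depth = 2L) {
  x_seq <- as.matrix(x_seq)
  if (nrow(x_seq) < 1L) abort_arg("`x_seq` must have at least one time step")
  X3 <- array(0, dim = c(1L, nrow(x_seq), ncol(x_seq)))
  X3[1L, , ] <- x_seq
  fw <- tree_batch_forward(X3, params, depth)
  list(s2 = as.numeric(fw$S2[1L, ]), y_r = as.numeric(fw$y_r[1L, ]))
}

## ---- Q agent ---------------------------------------------------------------

#' Running-average Q-learning target
#'
#' `(1/t) r + ((t-1)/t) q_prev`: the first visit returns the (bootstrapped)
#' reward itself; repeated visits average successive returns, so a constant
#' reward converges to that constant.
#'
#' @param r Observed return (reward plus any bootstrap term).
#' @param t Visit count for the state-action pair (>= 1).
#' @param q_prev The pair's previous value estimate.
#' @return The target value.
#' @export
q_target <- function(r, t, q_prev) {
  if (length(t) != 1L || !is.numeric(t) || is.na(t) || t < 1) {
    abort_arg("`t` must be a visit count >= 1")
  }
  (1 / t) * r + ((t - 1) / t) * q_prev
}

kind_index <- function(kind) {
  i <- match(kind, c("s1", "s2"))
  if (is.na(i)) abort_arg("`kind` must be 's1' or 's2' (terminal states take no action)")
  i
}

legal_actions <- function(kind) if (kind == "s1") c(1L, 2L) else c(3L, 4L)

# Q-network input: zero-padded state vector, state-kind one-hot, action
# one-hot.
q_input <- function(agent, svec, kind, action) {
  z <- numeric(agent$state_dim + 6L)
  z[seq_along(svec)] <- svec
  z[agent$state_dim + kind_index(kind)] <- 1
  z[agent$state_dim + 2L + action] <- 1
  z
}

#' Initialize a Q-network agent
#'
#' Two-layer perceptron (tanh hidden layer) over the padded state vector plus
#' state-kind and action one-hots, trained by RMSprop on the squared error to
#' the running-average target; per-(state-kind, action) visit counts drive
#' the target's averaging weight.
#'
#' @param state_dim Width of the widest decision-state vector.
#' @param hidden Hidden width of the Q-network.
#' @param lr RMSprop step size used when `q_update` is called without an
#'   explicit step.
#' @param seed Integer seed for initialization.
#' @return An object of class `q_agent`.
#' @export
q_agent <- function(state_dim, hidden = 16L, lr = 0.01, seed = 1L) {
  state_dim <- check_count(state_dim, "state_dim")
  hidden <- check_count(hidden, "hidden")
  with_seed(seed, {
    params <- list(Wq1 = glorot(state_dim + 6L, hidden), bq1 = numeric(hidden),
                   wq2 = stats::rnorm(hidden, sd = sqrt(1 / hidden)),
                   bq2 = 0)
    structure(list(params = params, opt = rmsprop_init(params),
                   counts = matrix(0L, 2L, 4L), state_dim = state_dim,
                   hidden = hidden, lr = lr),
              class = "q_agent")
  })
}

q_value <- function(agent, svec, kind, action) {
  z <- q_input(agent, svec, kind, action)
  h <- tanh(as.numeric(z %*% agent$params$Wq1) + as.numeric(agent$params$bq1))
  sum(h * as.numeric(agent$params$wq2)) + as.numeric(agent$params$bq2)
}

q_values_state <- function(agent, svec, kind) {
  vapply(legal_actions(kind), function(a) q_value(agent, svec, kind, a),
         numeric(1L))
}

#' Initialize a tabular Q agent
#'
#' Degenerate specialization storing one Q value and visit count per
#' state-action pair; `q_update` assigns the running-average target exactly.
#'
#' @param n_states,n_actions Table dimensions.
#' @return An object of class `q_agent_tabular`.
#' @export
q_agent_tabular <- function(n_states, n_actions) {
  structure(list(Q = matrix(0, n_states, n_actions),
                 counts = matrix(0L, n_states, n_actions)),
            class = "q_agent_tabular")
}

#' One Q-learning update from a transition
#'
#' Increments the pair's visit count `t`, forms the running-average target
#' [q_target()] of the bootstrapped return `r + max_a' Q(s', a')` (zero
#' bootstrap at the terminal state), and moves `Q(s, a)` toward it: a
#' RMSprop gradient step on the squared error for the network agent, exact
#' assignment for the tabular agent.
#'
#' @param agent A [q_agent()] or [q_agent_tabular()].
#' @param transition List with `state`, `kind` (`"s1"`/`"s2"`; network) or
#'   `state` index (tabular), `action`, `reward`, and `next_state` (`NULL`
#'   when the episode ends) plus `next_kind`.
#' @param alpha Step size; `0` leaves the agent unchanged.
#' @return The updated agent.
#' @export
q_update <- function(agent, transition, alpha = NULL) {
  UseMethod("q_update")
}

#' @export
q_update.q_agent <- function(agent, transition, alpha = NULL) {
  alpha <- alpha %||% agent$lr
  kind <- transition$kind
  action <- check_count(transition$action, "action")
  if (!(action %in% legal_actions(kind))) {
    abort_arg(sprintf("action a%d is not legal in state %s", action, kind))
  }
  ki <- kind_index(kind)
  agent$counts[ki, action] <- agent$counts[ki, action] + 1L
  t_visit <- agent$counts[ki, action]
  boot <- if (is.null(transition$next_state)) 0 else {
    max(q_values_state(agent, transition$next_state, transition$next_kind))
  }
  z <- q_input(agent, transition$state, kind, action)
  h <- tanh(as.numeric(z %*% agent$params$Wq1) + as.numeric(agent$params$bq1))
  q_sa <- sum(h * as.numeric(agent$params$wq2)) + as.numeric(agent$params$bq2)
  target <- q_target(transition$reward + boot, t_visit, q_sa)
  delta <- q_sa - target
  dpre <- (as.numeric(agent$params$wq2) * delta) * (1 - h^2)
  grads <- list(Wq1 = outer(z, dpre), bq1 = dpre, wq2 = h * delta, bq2 = delta)
  if (alpha > 0) {
    step <- rmsprop_step(agent$params, grads, agent$opt, alpha)
    agent$params <- step$params
    agent$opt <- step$state
  }
  agent
}

#' @export
q_update.q_agent_tabular <- function(agent, transition, alpha = NULL) {
  s <- check_count(transition$state, "state")
  a <- check_count(transition$action, "action")
  agent$counts[s, a] <- agent$counts[s, a] + 1L
  t_visit <- agent$counts[s, a]
  boot <- if (is.null(transition$next_state)) 0 else {
    max(agent$Q[transition$next_state, ])
  }
  agent$Q[s, a] <- q_target(transition$reward + boot, t_visit, agent$Q[s, a])
  agent
}

## ---- episodes and training -------------------------------------------------

# Internal episode over precomputed state vectors; used by training and by
# run_episode. pred1 is the stage-1 head's argmax (0-based).
episode_from_states <- function(agent, s1, s2_fn, pred1, label, explore_eps,
                                r_defer, forced_actions = NULL) {
  pick <- function(kind, svec, k) {
    acts <- legal_actions(kind)
    if (!is.null(forced_actions) && length(forced_actions) >= k) {
      a <- forced_actions[[k]]
      if (!(a %in% acts)) abort_arg(sprintf("forced action a%d illegal in %s", a, kind))
      return(a)
    }
    if (explore_eps > 0 && stats::runif(1L) < explore_eps) return(sample(acts, 1L))
    acts[which.max(q_values_state(agent, svec, kind))]
  }
  a1 <- pick("s1", s1, 1L)
  if (a1 == 1L) {
    r <- if (pred1 == label) 1 else -1
    return(list(transitions = list(list(state = s1, kind = "s1", action = 1L,
                                        reward = r, next_state = NULL,
                                        next_kind = NULL)),
                total_reward = r, prediction = pred1))
  }
  s2 <- s2_fn()
  a2 <- pick("s2", s2, 2L)
  pred <- a2 - 3L
  r <- if (pred == label) 1 else -1
  list(transitions = list(
    list(state = s1, kind = "s1", action = 2L, reward = r_defer,
         next_state = s2, next_kind = "s2"),
    list(state = s2, kind = "s2", action = a2, reward = r,
         next_state = NULL, next_kind = NULL)),
    total_reward = r_defer + r, prediction = pred)
}

#' Run one decision episode on a signal
#'
#' Builds `s1` from the BiLSTM + attention state builder; the agent commits
#' (`a1`, terminal reward +1/-1 against the stage-1 head's prediction) or
#' defers (`a2`, reward `r_defer`) to the Tree-LSTM state `s2`, where `a3`
#' predicts class 0 and `a4` class 1 (terminal reward +1/-1). Greedy when
#' `explore_eps = 0`.
#'
#' @param agent A [q_agent()].
#' @param model A trained (or initialized) `rbatq_model` providing the state
#'   builders, or a list with `theta_rnn`, `theta_tree`, `cfg`.
#' @param x One segment (numeric vector).
#' @param label The true class (0/1).
#' @param explore_eps Exploration rate.
#' @param forced_actions Optional integer vector overriding the agent's
#'   choices (e.g. `c(2L, 3L)` forces defer-then-class-0).
#' @return List with `transitions`, `total_reward` and the emitted
#'   `prediction`.
#' @export
run_episode <- function(agent, model, x, label, explore_eps = 0,
                        forced_actions = NULL) {
  cfg <- model$cfg
  X <- matrix(as.numeric(x), nrow = 1L)
  X3 <- frame_matrix(X, cfg$n_frames)
  fw <- bilstm_batch_forward(X3, model$theta_rnn)
  att <- att_batch_forward(fw$H, fw$Hp, model$theta_rnn)
  s <- dim(fw$H)[3L]
  logits <- att$S1[, seq_len(s), drop = FALSE] %*% model$theta_rnn$Why +
    att$S1[, s + seq_len(s), drop = FALSE] %*% model$theta_rnn$Wpy
  logits <- add_bias_rows(logits, model$theta_rnn$by)
  pred1 <- max.col(logits, ties.method = "first") - 1L
  s1 <- as.numeric(att$S1[1L, ])
  s2_fn <- function() {
    as.numeric(tree_batch_forward(X3, model$theta_tree, cfg$tree_depth)$S2[1L, ])
  }
  episode_from_states(agent, s1, s2_fn, pred1, label, explore_eps,
                      cfg$r_defer, forced_actions)
}

#' Train the RBATQ classifier
#'
#' Phase 1 pre-trains the BiLSTM + attention head and the Tree-LSTM head by
#' supervised cross-entropy (RMSprop, max-norm constraint on state-builder
#' weights, dropout on pooled states). Phase 2 freezes the state builders,
#' precomputes `s1`/`s2` for every signal, and runs epsilon-greedy Q-learning
#' episodes, updating the Q-network from every transition. Deterministic
#' under `cfg$seed`.
#'
#' @param data An `eeg_segment_set` or numeric matrix of segments.
#' @param labels Labels when `data` is a matrix (ignored for segment sets).
#' @param cfg An [rbatq_config()].
#' @return An `rbatq_model` with state builders, agent, and reward/loss
#'   traces.
#' @export
train_rbatq <- function(data, cfg = rbatq_config(), labels = NULL) {
  if (!inherits(cfg, "rbatq_config")) abort_arg("`cfg` must be an rbatq_config")
  if (inherits(data, "eeg_segment_set")) {
    y <- data$labels
    X3 <- frame_segment_set(data, cfg$n_frames)
  } else {
    if (is.null(labels)) abort_arg("`labels` required for matrix input")
    y <- as.integer(labels)
    X3 <- frame_matrix(as.matrix(data), cfg$n_frames)
  }
  if (length(unique(y)) < 2L) abort_arg("training data must contain both classes")
  n <- dim(X3)[1L]
  f_dim <- dim(X3)[3L]
  with_seed(cfg$seed, {
    theta_rnn <- init_bilstm_params(f_dim, cfg$state_size, cfg$hidden, cfg$n_classes)
    leaf_dim <- (cfg$n_frames %/% 2L^cfg$tree_depth) * f_dim
    theta_tree <- init_tree_params(leaf_dim, cfg$state_size, cfg$n_classes)

    rnn_weight_names <- grep("^(f|b)_W|^Wa$", names(theta_rnn), value = TRUE)
    tree_weight_names <- grep("^[WU]", names(theta_tree), value = TRUE)

    pretrain <- function(params, loss_fn, weight_names, state_width) {
      opt <- rmsprop_init(params)
      trace <- numeric(cfg$pretrain_epochs)
      bs <- min(cfg$batch_size, n)
      keep <- 1 - cfg$dropout_rate
      for (epoch in seq_len(cfg$pretrain_epochs)) {
        idx <- sample.int(n)
        for (start in seq(1L, n, by = bs)) {
          take <- idx[start:min(start + bs - 1L, n)]
          Xb <- X3[take, , , drop = FALSE]
          mask <- NULL
          if (cfg$dropout_rate > 0) {
            mask <- matrix(stats::rbinom(length(take) * state_width, 1L, keep) / keep,
                           length(take), state_width)
          }
          lg <- loss_fn(params, Xb, y[take], mask)
          if (!is.finite(lg$cost)) abort_training(sprintf("non-finite loss at epoch %d", epoch))
          step <- rmsprop_step(params, lg$grads, opt, cfg$learning_rate)
          params <- apply_max_norm(step$params, cfg$max_norm, weight_names)
          opt <- step$state
        }
        trace[epoch] <- loss_fn(params, X3, y, NULL)$cost
      }
      list(params = params, trace = trace)
    }

    pr <- pretrain(theta_rnn,
                   function(p, Xb, yb, mask) bilstm_att_loss(p, Xb, yb, cfg$n_classes, mask),
                   rnn_weight_names, 2L * cfg$state_size)
    theta_rnn <- pr$params
    pt <- pretrain(theta_tree,
                   function(p, Xb, yb, mask) tree_loss(p, Xb, yb, cfg$n_classes,
                                                       cfg$tree_depth, mask),
                   tree_weight_names, cfg$state_size)
    theta_tree <- pt$params

    # frozen state builders: precompute decision states and stage-1 preds
    final_rnn <- bilstm_att_loss(theta_rnn, X3, y, cfg$n_classes, NULL)
    S1 <- final_rnn$S1
    pred1 <- max.col(final_rnn$prob, ties.method = "first") - 1L
    final_tree <- tree_loss(theta_tree, X3, y, cfg$n_classes, cfg$tree_depth, NULL)
    S2 <- final_tree$S2

    agent <- q_agent(state_dim = max(2L * cfg$state_size, cfg$state_size),
                     hidden = cfg$hidden, lr = cfg$learning_rate,
                     seed = derive_seed(cfg$seed, 77L))
    reward_trace <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      eps <- if (cfg$epochs == 1L) cfg$eps_end else {
        cfg$eps_start + (cfg$eps_end - cfg$eps_start) * (epoch - 1L) / (cfg$epochs - 1L)
      }
      total <- 0
      for (i in sample.int(n)) {
        ep <- episode_from_states(agent, S1[i, ], function() S2[i, ],
                                  pred1[i], y[i], eps, cfg$r_defer)
        for (tr in ep$transitions) agent <- q_update(agent, tr)
        total <- total + ep$total_reward
      }
      reward_trace[epoch] <- total / n
    }

    structure(list(theta_rnn = theta_rnn, theta_tree = theta_tree,
                   agent = agent, cfg = cfg, trained = TRUE,
                   pretrain_trace_rnn = pr$trace,
                   pretrain_trace_tree = pt$trace,
                   reward_trace = reward_trace),
              class = "rbatq_model")
  })
}

#' Predict labels with a trained RBATQ model
#'
#' Greedy rollout of the control policy: the label comes from the committed
#' action (`a1` = recurrent head's argmax, `a3`/`a4` = class 0/1).
#'
#' @param model A trained `rbatq_model`.
#' @param data An `eeg_segment_set` or matrix of segments.
#' @return List with integer `labels` and the stage-1 decision `actions`.
#' @export
rbatq_predict <- function(model, data) {
  if (!inherits(model, "rbatq_model")) abort_state("`model` must be an rbatq_model")
  if (!isTRUE(model$trained)) abort_state("model has not been trained")
  cfg <- model$cfg
  X3 <- if (inherits(data, "eeg_segment_set")) {
    frame_segment_set(data, cfg$n_frames)
  } else {
    frame_matrix(as.matrix(data), cfg$n_frames)
  }
  n <- dim(X3)[1L]
  fw <- bilstm_batch_forward(X3, model$theta_rnn)
  att <- att_batch_forward(fw$H, fw$Hp, model$theta_rnn)
  s <- dim(fw$H)[3L]
  logits <- add_bias_rows(
    att$S1[, seq_len(s), drop = FALSE] %*% model$theta_rnn$Why +
      att$S1[, s + seq_len(s), drop = FALSE] %*% model$theta_rnn$Wpy,
    model$theta_rnn$by)
  pred1 <- max.col(logits, ties.method = "first") - 1L
  S2 <- tree_batch_forward(X3, model$theta_tree, cfg$tree_depth)$S2
  labels <- integer(n)
  actions <- integer(n)
  for (i in seq_len(n)) {
    q1 <- q_values_state(model$agent, att$S1[i, ], "s1")
    if (which.max(q1) == 1L) {
      labels[i] <- pred1[i]
      actions[i] <- 1L
    } else {
      q2 <- q_values_state(model$agent, S2[i, ], "s2")
      labels[i] <- which.max(q2) - 1L
      actions[i] <- 2L
    }
  }
  list(labels = labels, actions = actions)
}
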