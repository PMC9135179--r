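zero_params <- function(p) lapply(p, function(x) x * 0)

test_that("zero-parameter BiLSTM sits at the h = c = 0 fixed point with uniform softmax", {
  params <- zero_params(eegdeep:::with_seed(1L, eegdeep:::init_bilstm_params(3L, 4L, 5L, 2L)))
  x_seq <- matrix(stats::rnorm(15L), 5L, 3L)
  out <- bilstm_forward(x_seq, params)
  # sigma(0) = 0.5 gates, tanh(0) = 0 candidate: c_t = 0.5 * 0 + 0.5 * 0 = 0
  expect_equal(out$h_seq, matrix(0, 5L, 4L))
  expect_equal(out$hp_seq, matrix(0, 5L, 4L))
  expect_equal(out$y_seq, matrix(0.5, 5L, 2L))
})

test_that("per-step softmax rows always sum to one", {
  params <- eegdeep:::with_seed(2L, eegdeep:::init_bilstm_params(3L, 4L, 5L, 2L))
  out <- bilstm_forward(matrix(stats::rnorm(12L), 4L, 3L), params)
  expect_equal(rowSums(out$y_seq), rep(1, 4L), tolerance = 1e-6)
})

test_that("reversing the input swaps the roles of the two directions", {
  params <- eegdeep:::with_seed(3L, eegdeep:::init_bilstm_params(2L, 3L, 4L, 2L))
  # share the cell parameters across directions so the symmetry is exact
  for (nm in grep("^f_", names(params), value = TRUE)) {
    params[[sub("^f_", "b_", nm)]] <- params[[nm]]
  }
  x <- matrix(stats::rnorm(6L), 3L, 2L)
  fwd <- bilstm_forward(x, params)
  rev_out <- bilstm_forward(x[3:1, , drop = FALSE], params)
  for (t in 1:3) {
    expect_equal(fwd$h_seq[t, ], rev_out$hp_seq[4L - t, ], tolerance = 1e-12)
  }
})

test_that("attention pooling is a proper convex combination over time", {
  params <- eegdeep:::with_seed(4L, eegdeep:::init_bilstm_params(2L, 3L, 4L, 2L))
  one <- attention_state(matrix(1:3, 1L), matrix(4:6, 1L), params)
  expect_equal(one$weights, 1)
  expect_equal(one$s1, c(1, 2, 3, 4, 5, 6))
  h <- matrix(rep(c(0.3, -0.2, 0.5), each = 4L), 4L)
  hp <- matrix(rep(c(0.1, 0.9, -0.4), each = 4L), 4L)
  same <- attention_state(h, hp, params)
  expect_equal(same$s1, c(0.3, -0.2, 0.5, 0.1, 0.9, -0.4), tolerance = 1e-12)
  rnd <- attention_state(matrix(stats::rnorm(12L), 4L), matrix(stats::rnorm(12L), 4L), params)
  expect_equal(sum(rnd$weights), 1, tolerance = 1e-6)
  expect_true(all(rnd$weights >= 0))
})

test_that("tree state output head is a probability and leaf locality holds", {
  params <- eegdeep:::with_seed(5L, eegdeep:::init_tree_params(4L, 3L, 2L))
  x_seq <- matrix(stats::rnorm(8L), 4L, 2L)        # 4 frames, depth 1: 2 leaves
  out <- tree_state(x_seq, params, depth = 1L)
  expect_equal(sum(out$y_r), 1, tolerance = 1e-6)
  expect_length(out$s2, 3L)
  # disturb only leaf 2's chunk: leaf 1's node state is untouched, root moves
  X3a <- array(0, dim = c(1L, 4L, 2L)); X3a[1L, , ] <- x_seq
  x_mod <- x_seq; x_mod[3:4, ] <- x_mod[4:3, ]
  X3b <- array(0, dim = c(1L, 4L, 2L)); X3b[1L, , ] <- x_mod
  fa <- eegdeep:::tree_batch_forward(X3a, params, 1L)
  fb <- eegdeep:::tree_batch_forward(X3b, params, 1L)
  expect_equal(fa$levels[[1L]][[1L]]$h, fb$levels[[1L]][[1L]]$h)
  expect_false(isTRUE(all.equal(fa$levels[[1L]][[2L]]$h, fb$levels[[1L]][[2L]]$h)))
  expect_false(isTRUE(all.equal(fa$S2, fb$S2)))
  # degenerate depth-0 tree: a single leaf embeds the whole sequence
  params0 <- eegdeep:::with_seed(6L, eegdeep:::init_tree_params(8L, 3L, 2L))
  single <- tree_state(x_seq, params0, depth = 0L)
  expect_length(single$s2, 3L)
  expect_equal(sum(single$y_r), 1, tolerance = 1e-6)
})

test_that("recurrent and tree losses match the finite-difference oracle", {
  p <- eegdeep:::with_seed(7L, eegdeep:::init_bilstm_params(3L, 4L, 5L, 2L))
  X3 <- array(stats::rnorm(2L * 6L * 3L), dim = c(2L, 6L, 3L))
  y <- c(0L, 1L)
  an <- eegdeep:::bilstm_att_loss(p, X3, y, 2L)$grads
  nu <- num_grad(function(pp) eegdeep:::bilstm_att_loss(pp, X3, y, 2L)$cost, p)
  expect_lt(grad_rel_err(an, nu), 1e-4)

  tp <- eegdeep:::with_seed(9L, eegdeep:::init_tree_params(6L, 4L, 2L))
  X3b <- array(stats::rnorm(3L * 8L * 3L), dim = c(3L, 8L, 3L))
  yb <- c(0L, 1L, 1L)
  an <- eegdeep:::tree_loss(tp, X3b, yb, 2L, 2L)$grads
  nu <- num_grad(function(pp) eegdeep:::tree_loss(pp, X3b, yb, 2L, 2L)$cost, tp)
  expect_lt(grad_rel_err(an, nu), 1e-4)
})

test_that("q_target is the visit-count running average", {
  expect_equal(q_target(1, 1L, 99), 1)             # first visit ignores q_prev
  expect_equal(q_target(1, 2L, 0.5), 0.75)         # 0.5*1 + 0.5*0.5
  expect_error(q_target(1, 0L, 0), class = "eegdeep_argument_error")
  # constant reward c converges to c
  agent <- q_agent_tabular(3L, 4L)
  for (i in 1:200) {
    agent <- q_update(agent, list(state = 1L, action = 1L, reward = 0.7,
                                  next_state = NULL))
  }
  expect_lt(abs(agent$Q[1L, 1L] - 0.7), 1e-3)
})

test_that("tabular q_update reproduces the running average of bootstrapped returns", {
  agent <- q_agent_tabular(3L, 4L)
  rewards <- c(1, 0, 1, 1)
  for (r in rewards) {
    agent <- q_update(agent, list(state = 2L, action = 3L, reward = r,
                                  next_state = NULL))
  }
  expect_equal(agent$Q[2L, 3L], mean(rewards))
})

test_that("the greedy tabular policy matches the value-iteration oracle on the toy MDP", {
  mdp <- toy_mdp()
  oracle <- value_iteration_oracle(mdp)
  agent <- q_agent_tabular(3L, 4L)
  eegdeep:::with_seed(21L, {
    for (ep in 1:300) {
      s <- 1L
      while (s != 3L) {
        acts <- mdp$legal[[as.character(s)]]
        a <- if (stats::runif(1L) < 0.3) sample(acts, 1L) else acts[which.max(agent$Q[s, acts])]
        tr <- mdp$step(s, a)
        agent <- q_update(agent, list(state = s, action = a, reward = tr$r,
                                      next_state = if (tr$s_next == 3L) NULL else tr$s_next))
        s <- tr$s_next
      }
    }
  })
  for (s in 1:2) {
    acts <- mdp$legal[[as.character(s)]]
    expect_equal(acts[which.max(agent$Q[s, acts])], acts[which.max(oracle[s, acts])])
  }
  # learned values approximate the oracle's optimal values
  expect_equal(agent$Q[1L, 2L], oracle[1L, 2L], tolerance = 0.05)
  expect_equal(agent$Q[2L, 3L], oracle[2L, 3L], tolerance = 0.05)
})

test_that("a zero step size leaves the network agent untouched", {
  agent <- q_agent(6L, hidden = 4L, seed = 1L)
  before <- agent$params
  tr <- list(state = stats::rnorm(6L), kind = "s1", action = 1L, reward = 1,
             next_state = NULL)
  after <- q_update(agent, tr, alpha = 0)
  expect_identical(after$params, before)
  expect_equal(after$counts[1L, 1L], 1L)           # the visit still counts
})

test_that("network q_update moves the estimate toward a frozen target", {
  agent <- q_agent(4L, hidden = 8L, seed = 2L)
  s <- stats::rnorm(4L)
  q0 <- eegdeep:::q_value(agent, s, "s1", 1L)
  for (i in 1:50) {
    agent <- q_update(agent, list(state = s, kind = "s1", action = 1L,
                                  reward = 1, next_state = NULL), alpha = 0.05)
  }
  q1 <- eegdeep:::q_value(agent, s, "s1", 1L)
  expect_lt(abs(q1 - 1), abs(q0 - 1))
  expect_error(q_update(agent, list(state = s, kind = "s_e", action = 1L,
                                    reward = 0, next_state = NULL)),
               class = "eegdeep_argument_error")
  expect_error(q_update(agent, list(state = s, kind = "s1", action = 3L,
                                    reward = 0, next_state = NULL)),
               class = "eegdeep_argument_error")
})

test_that("episodes follow the two-stage decision structure", {
  builders <- tiny_builders()
  agent <- q_agent(2L * 3L, hidden = 4L, seed = 3L)
  x <- eegdeep:::with_seed(8L, stats::rnorm(16L))
  # forced commit: single terminal transition with a +/-1 reward
  ep1 <- run_episode(agent, builders, x, label = 0L, forced_actions = 1L)
  expect_length(ep1$transitions, 1L)
  expect_identical(ep1$transitions[[1L]]$kind, "s1")
  expect_true(ep1$transitions[[1L]]$reward %in% c(-1, 1))
  expect_null(ep1$transitions[[1L]]$next_state)
  # forced defer then predict class 0: two transitions, defer reward then +/-1
  ep2 <- run_episode(agent, builders, x, label = 0L, forced_actions = c(2L, 3L))
  expect_length(ep2$transitions, 2L)
  expect_equal(ep2$transitions[[1L]]$reward, builders$cfg$r_defer)
  expect_identical(ep2$transitions[[2L]]$kind, "s2")
  expect_equal(ep2$prediction, 0L)
  expect_equal(ep2$total_reward, builders$cfg$r_defer + 1)
  # greedy episodes are deterministic
  ep3 <- run_episode(agent, builders, x, label = 1L, explore_eps = 0)
  ep4 <- run_episode(agent, builders, x, label = 1L, explore_eps = 0)
  expect_identical(ep3, ep4)
  expect_error(run_episode(agent, builders, x, 0L, forced_actions = 3L),
               class = "eegdeep_argument_error")
})

test_that("training learns separable data and stays at chance on permuted labels", {
  pool <- normalize_segments(small_pool(4L, seed = 9L))   # 184 segments
  X <- pool$segments; y <- pool$labels
  cfg <- rbatq_config(state_size = 8L, hidden = 8L, n_frames = 8L,
                      tree_depth = 2L, dropout_rate = 0, learning_rate = 0.02,
                      batch_size = 25L, pretrain_epochs = 25L, epochs = 6L,
                      seed = 2L)
  model <- train_rbatq(X, cfg, labels = y)
  acc <- mean(rbatq_predict(model, X)$labels == y)
  expect_gte(acc, 0.9)
  # reward trace is reproducible under the seed
  model2 <- train_rbatq(X, cfg, labels = y)
  expect_identical(model$reward_trace, model2$reward_trace)
  # permuted labels: held-out accuracy at chance
  y_perm <- eegdeep:::with_seed(13L, sample(y))
  tr <- seq_len(120L); te <- 121:184
  m_perm <- train_rbatq(X[tr, ], cfg, labels = y_perm[tr])
  acc_perm <- mean(rbatq_predict(m_perm, X[te, ])$labels == y_perm[te])
  expect_lt(abs(acc_perm - 0.5), 0.15)
  expect_error(train_rbatq(X, cfg, labels = rep(0L, nrow(X))),
               class = "eegdeep_argument_error")
})
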