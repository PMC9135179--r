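sphere <- function(x) -sum(x^2)

test_that("pso_step is a fixed point when position, bests and velocity agree", {
  swarm <- list(positions = matrix(1, 3L, 4L), velocities = matrix(0, 3L, 4L),
                pbest_pos = matrix(1, 3L, 4L), pbest_fit = rep(0, 3L))
  out <- pso_step(swarm, rep(1, 4L), pso_config())
  expect_equal(out$positions, swarm$positions)
  expect_equal(out$velocities, swarm$velocities)
})

test_that("pso_step reproduces the hand-evaluated update under forced randomness", {
  # w = 0.64, c1 = c2 = 1.524, r1 = r2 = 0.5, v = 0, x = 0, bests = 1:
  # v' = 1.524 * 0.5 * 1 + 1.524 * 0.5 * 1 = 1.524, x' = 1.524
  swarm <- list(positions = matrix(0, 1L, 1L), velocities = matrix(0, 1L, 1L),
                pbest_pos = matrix(1, 1L, 1L), pbest_fit = 0)
  out <- pso_step(swarm, 1, pso_config(), r1 = 0.5, r2 = 0.5)
  expect_equal(out$velocities[1L, 1L], 1.524)
  expect_equal(out$positions[1L, 1L], 1.524)
})

test_that("pso_step validates dimensions", {
  swarm <- list(positions = matrix(0, 2L, 3L), velocities = matrix(0, 2L, 3L),
                pbest_pos = matrix(0, 2L, 3L), pbest_fit = rep(0, 2L))
  expect_error(pso_step(swarm, rep(0, 2L), pso_config()),
               class = "eegdeep_argument_error")
})

test_that("all three optimizers keep monotone best-so-far traces and are seed-deterministic", {
  for (runner in list(
    function(s) run_pso(sphere, 4L, pso_config(n_particles = 8L, generations = 15L, seed = s)),
    function(s) run_cso(sphere, 4L, cso_config(n_nests = 8L, generations = 15L, seed = s)),
    function(s) run_ba(sphere, 4L, ba_config(n_bats = 8L, generations = 15L, seed = s)))) {
    a <- runner(3L)
    expect_true(all(diff(a$trace) >= 0))
    expect_identical(a$trace, runner(3L)$trace)
    expect_false(identical(a$trace, runner(4L)$trace))
  }
})

test_that("a particle seeded at the optimum remains the global best", {
  res <- run_pso(sphere, 3L, pso_config(n_particles = 2L, generations = 10L, seed = 1L),
                 init_mean = c(0, 0, 0))
  expect_equal(res$best_fitness, 0)
  expect_equal(res$best_position, c(0, 0, 0))
  expect_true(all(res$trace == 0))
})

test_that("levy_step honours the zero-step and dimension contracts", {
  x <- c(1, 2, 3)
  expect_identical(levy_step(x, alpha = 0), x)
  expect_length(levy_step(x, alpha = 1.5), 3L)
  expect_error(levy_step(x, 1.5, levy_lambda = 0.5), class = "eegdeep_argument_error")
  expect_error(levy_step(x, 1.5, levy_lambda = 3.5), class = "eegdeep_argument_error")
})

test_that("Mantegna steps have the requested power-law tail index", {
  draws <- eegdeep:::with_seed(10L, abs(eegdeep:::levy_draw(1e5L, 1.5)))
  tail_draws <- sort(draws, decreasing = TRUE)[1:2000]
  # rank regression: log(rank) ~ -lambda * log(value)
  fit <- stats::lm(log(seq_along(tail_draws)) ~ log(tail_draws))
  expect_equal(unname(-stats::coef(fit)[2L]), 1.5, tolerance = 0.2)
})

test_that("cuckoo abandonment fractions hit their boundary semantics", {
  none <- run_cso(sphere, 3L, cso_config(n_nests = 6L, p_abandon = 0,
                                         generations = 5L, seed = 1L))
  expect_true(all(none$n_abandoned == 0L))
  all_but_best <- run_cso(sphere, 3L, cso_config(n_nests = 6L, p_abandon = 1,
                                                 generations = 5L, seed = 1L))
  expect_true(all(all_but_best$n_abandoned == 5L))
})

test_that("a silent bat colony (zero loudness) never updates its best", {
  res <- run_ba(sphere, 3L, ba_config(n_bats = 6L, loudness = 0,
                                      generations = 10L, seed = 2L))
  expect_true(all(res$trace == res$trace[1L]))
})

test_that("mask decoding selects top-m with index tie-breaks", {
  m1 <- mask_from_position(c(0.9, 0.1, 0.5, 0.7), 2L)
  expect_identical(which(m1$selected), c(1L, 4L))
  ties <- mask_from_position(rep(1, 5L), 2L)
  expect_identical(which(ties$selected), c(1L, 2L))
  big <- mask_from_position(eegdeep:::with_seed(1L, stats::runif(9000L)), 4500L)
  expect_equal(sum(big$selected), 4500L)
  expect_error(mask_from_position(c(1, 2), 3L), class = "eegdeep_argument_error")
})

test_that("wrapper fitness separates informative masks from noise masks", {
  pr <- make_recovery_problem(1L, n = 200L, d = 12L, n_info = 5L, effect = 2)
  info_mask <- mask_from_position(c(rep(1, 5L), rep(0, 7L)), 5L)
  noise_mask <- mask_from_position(c(rep(0, 5L), rep(1, 7L)), 5L)
  f_info <- feature_fitness(info_mask, pr$X, pr$y, split_seed = 1L)
  f_noise <- feature_fitness(noise_mask, pr$X, pr$y, split_seed = 1L)
  expect_gt(f_info, 0.9)
  expect_lt(abs(f_noise - 0.5), 0.15)
  expect_identical(f_info, feature_fitness(info_mask, pr$X, pr$y, split_seed = 1L))
  expect_error(feature_fitness(info_mask, pr$X, rep(0L, 200L)),
               class = "eegdeep_argument_error")
})

test_that("select_features returns a mask of the requested size with its trace", {
  pr <- make_recovery_problem(2L, n = 120L, d = 10L, n_info = 4L, effect = 1.5)
  sel <- select_features(pr$X, pr$y, m = 4L, method = "pso",
                         cfg = pso_config(n_particles = 6L, generations = 4L, seed = 1L),
                         split_seed = 1L)
  expect_equal(sum(sel$mask$selected), 4L)
  expect_true(all(diff(sel$result$trace) >= 0))
  expect_equal(sel$fitness, max(sel$result$trace))
})
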