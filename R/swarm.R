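# Swarm optimizers used as wrapper feature selectors: particle swarm
# optimization, cuckoo search with Mantegna Lévy flights, and the bat
# algorithm. All three maximize a user-supplied fitness over continuous
# positions; positions are decoded to feature masks by top-m thresholding.

#' Particle swarm configuration
#'
#' Defaults follow the published operating point: inertia 0.64, acceleration
#' coefficients c1 = c2 = 1.524, 30 particles, 30 generations.
#' @param n_particles Population size (>= 2).
#' @param generations Number of generations.
#' @param inertia Inertia weight `w`.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param init_sd Standard deviation of the Gaussian position initialization.
#' @param seed Integer seed.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(n_particles = 30L, generations = 30L, inertia = 0.64,
                       c1 = 1.524, c2 = 1.524, init_sd = 1, seed = 1L) {
  structure(list(n_particles = check_count(n_particles, "n_particles", min = 2L),
                 generations = check_count(generations, "generations"),
                 inertia = check_scalar(inertia, "inertia", lower = 0),
                 c1 = check_scalar(c1, "c1", lower = 0),
                 c2 = check_scalar(c2, "c2", lower = 0),
                 init_sd = check_scalar(init_sd, "init_sd", lower = 1e-12),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pso_config")
}

#' Cuckoo search configuration
#'
#' Defaults follow the published operating point: 20 nests, abandonment
#' probability 0.45, step size 1.5 with Lévy exponent 1.5.
#' @param n_nests Number of host nests (>= 2).
#' @param p_abandon Fraction of worse nests abandoned per generation, in [0,1].
#' @param alpha Lévy step-size factor.
#' @param levy_lambda Lévy tail exponent in (1, 3].
#' @param generations Number of generations.
#' @param init_sd Initialization spread.
#' @param seed Integer seed.
#' @return A list of class `cso_config`.
#' @export
cso_config <- function(n_nests = 20L, p_abandon = 0.45, alpha = 1.5,
                       levy_lambda = 1.5, generations = 30L, init_sd = 1,
                       seed = 1L) {
  if (p_abandon < 0 || p_abandon > 1) abort_arg("`p_abandon` must be in [0, 1]")
  if (levy_lambda <= 1 || levy_lambda > 3) abort_arg("`levy_lambda` must be in (1, 3]")
  structure(list(n_nests = check_count(n_nests, "n_nests", min = 2L),
                 p_abandon = as.numeric(p_abandon),
                 alpha = check_scalar(alpha, "alpha", lower = 0),
                 levy_lambda = as.numeric(levy_lambda),
                 generations = check_count(generations, "generations"),
                 init_sd = check_scalar(init_sd, "init_sd", lower = 1e-12),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cso_config")
}

#' Bat algorithm configuration
#'
#' Defaults follow the published operating point: 40 virtual bats, initial
#' loudness 1 and initial pulse emission rate 0.5. Loudness decay and pulse
#' growth constants use the canonical value 0.9.
#' @param n_bats Number of bats (>= 2).
#' @param f_min,f_max Frequency range.
#' @param loudness Initial loudness `A0`.
#' @param pulse_rate Initial pulse emission rate `r0` in [0, 1].
#' @param alpha_loudness Loudness decay multiplier on acceptance.
#' @param gamma Pulse-rate growth constant.
#' @param generations Number of generations.
#' @param init_sd Initialization spread.
#' @param seed Integer seed.
#' @return A list of class `ba_config`.
#' @export
ba_config <- function(n_bats = 40L, f_min = 0, f_max = 2, loudness = 1,
                      pulse_rate = 0.5, alpha_loudness = 0.9, gamma = 0.9,
                      generations = 30L, init_sd = 1, seed = 1L) {
  if (f_min > f_max) abort_arg("`f_min` must not exceed `f_max`")
  if (pulse_rate < 0 || pulse_rate > 1) abort_arg("`pulse_rate` must be in [0, 1]")
  structure(list(n_bats = check_count(n_bats, "n_bats", min = 2L),
                 f_min = as.numeric(f_min), f_max = as.numeric(f_max),
                 loudness = check_scalar(loudness, "loudness", lower = 0),
                 pulse_rate = as.numeric(pulse_rate),
                 alpha_loudness = check_scalar(alpha_loudness, "alpha_loudness",
                                               lower = 0, upper = 1),
                 gamma = check_scalar(gamma, "gamma", lower = 0),
                 generations = check_count(generations, "generations"),
                 init_sd = check_scalar(init_sd, "init_sd", lower = 1e-12),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "ba_config")
}

#' One particle-swarm kinematic update
#'
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, then `x <- x + v`, with
#' fresh `r1, r2 ~ U(0,1)` per particle and dimension (or forced scalars for
#' testing). Fitness bookkeeping lives in [run_pso()].
#'
#' @param swarm List with matrices `positions`, `velocities`, `pbest_pos`
#'   (rows = particles).
#' @param global_best Numeric vector, the swarm's best-known position.
#' @param cfg A [pso_config()].
#' @param r1,r2 Optional forced values replacing the uniform draws.
#' @return The updated swarm.
#' @export
pso_step <- function(swarm, global_best, cfg, r1 = NULL, r2 = NULL) {
  x <- swarm$positions
  if (nrow(x) == 0L) abort_arg("swarm must be non-empty")
  if (length(global_best) != ncol(x)) abort_arg("`global_best` dimension mismatch")
  if (ncol(swarm$velocities) != ncol(x) || ncol(swarm$pbest_pos) != ncol(x)) {
    abort_arg("swarm matrices disagree in dimension")
  }
  draw <- function(forced) {
    if (is.null(forced)) matrix(stats::runif(length(x)), nrow(x), ncol(x))
    else matrix(forced, nrow(x), ncol(x))
  }
  R1 <- draw(r1); R2 <- draw(r2)
  gb <- matrix(global_best, nrow(x), ncol(x), byrow = TRUE)
  v <- cfg$inertia * swarm$velocities +
    cfg$c1 * R1 * (swarm$pbest_pos - x) +
    cfg$c2 * R2 * (gb - x)
  swarm$velocities <- v
  swarm$positions <- x + v
  swarm
}

#' Maximize a fitness with particle swarm optimization
#'
#' Personal and global bests are updated only on strict improvement; the
#' best-so-far trace is therefore monotone non-decreasing.
#'
#' @param fitness Function mapping a position vector to a scalar (maximized).
#' @param d Search dimension.
#' @param cfg A [pso_config()].
#' @param init_mean Optional length-`d` vector around which the population is
#'   initialized (the first individual starts exactly there); defaults to the
#'   origin.
#' @return List with `best_position`, `best_fitness`, and per-generation
#'   best-so-far `trace` (element 1 is the post-initialization best).
#' @export
run_pso <- function(fitness, d, cfg = pso_config(), init_mean = NULL) {
  d <- check_count(d, "d")
  with_seed(cfg$seed, {
    x <- init_population(cfg$n_particles, d, cfg$init_sd, init_mean)
    swarm <- list(positions = x,
                  velocities = matrix(0, cfg$n_particles, d),
                  pbest_pos = x,
                  pbest_fit = apply(x, 1L, fitness))
    gi <- which.max(swarm$pbest_fit)
    gbest_pos <- swarm$pbest_pos[gi, ]
    gbest_fit <- swarm$pbest_fit[gi]
    trace <- numeric(cfg$generations + 1L)
    trace[1L] <- gbest_fit
    for (gen in seq_len(cfg$generations)) {
      swarm <- pso_step(swarm, gbest_pos, cfg)
      fit <- apply(swarm$positions, 1L, fitness)
      improved <- fit > swarm$pbest_fit
      swarm$pbest_pos[improved, ] <- swarm$positions[improved, , drop = FALSE]
      swarm$pbest_fit[improved] <- fit[improved]
      bi <- which.max(swarm$pbest_fit)
      if (swarm$pbest_fit[bi] > gbest_fit) {
        gbest_fit <- swarm$pbest_fit[bi]
        gbest_pos <- swarm$pbest_pos[bi, ]
      }
      trace[gen + 1L] <- gbest_fit
    }
    list(best_position = gbest_pos, best_fitness = gbest_fit, trace = trace)
  })
}

#' Heavy-tailed Lévy flight step (Mantegna construction)
#'
#' Returns `x + alpha * s` where each entry of `s` is `u / |v|^(1/lambda)`
#' with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and Mantegna's sigma for tail
#' exponent `lambda`; step magnitudes follow a power law with tail index
#' `lambda`.
#'
#' @param x Position vector.
#' @param alpha Step-size factor (entry-wise product with the Lévy draw).
#' @param levy_lambda Tail exponent in (1, 3].
#' @return The displaced position vector.
#' @export
levy_step <- function(x, alpha, levy_lambda = 1.5) {
  if (levy_lambda <= 1 || levy_lambda > 3) abort_arg("`levy_lambda` must be in (1, 3]")
  x + alpha * levy_draw(length(x), levy_lambda)
}

# Gaussian population around an optional centre; the first individual sits
# exactly at the centre so a good seed position is always in the population.
init_population <- function(n, d, sd, init_mean = NULL) {
  x <- matrix(stats::rnorm(n * d, sd = sd), n, d)
  if (!is.null(init_mean)) {
    if (length(init_mean) != d) abort_arg("`init_mean` must have length d")
    x <- sweep(x, 2L, init_mean, "+")
    x[1L, ] <- init_mean
  }
  x
}

levy_draw <- function(n, lambda) {
  sigma_u <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
                (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
  u <- stats::rnorm(n, sd = sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / lambda)
}

#' Maximize a fitness with cuckoo search
#'
#' Per generation: one cuckoo solution is generated by a Lévy flight from a
#' random nest (step scaled by the distance to the best nest, the canonical
#' scaling), and replaces a randomly chosen nest if strictly fitter; then the
#' worst `ceiling(p_abandon * n)` nests, excluding the best (elitism), are
#' abandoned and rebuilt by a biased random walk between two random nests.
#'
#' @param fitness Function mapping a position vector to a scalar (maximized).
#' @param d Search dimension.
#' @param cfg A [cso_config()].
#' @param init_mean Optional initialization centre (see [run_pso()]).
#' @return List with `best_position`, `best_fitness`, best-so-far `trace`,
#'   and `n_abandoned` per generation.
#' @export
run_cso <- function(fitness, d, cfg = cso_config(), init_mean = NULL) {
  d <- check_count(d, "d")
  with_seed(cfg$seed, {
    n <- cfg$n_nests
    nests <- init_population(n, d, cfg$init_sd, init_mean)
    fit <- apply(nests, 1L, fitness)
    best_i <- which.max(fit)
    best_pos <- nests[best_i, ]
    best_fit <- fit[best_i]
    trace <- numeric(cfg$generations + 1L)
    trace[1L] <- best_fit
    n_abandoned <- integer(cfg$generations)
    for (gen in seq_len(cfg$generations)) {
      # Lévy phase: every nest spawns a cuckoo by a Lévy flight scaled by its
      # distance to the best nest (canonical Mantegna scaling). The first
      # cuckoo of the generation is dropped into a randomly chosen nest and
      # replaces it if strictly fitter; the remainder compete greedily with
      # their own source nest.
      for (src in seq_len(n)) {
        step <- cfg$alpha * 0.01 * levy_draw(d, cfg$levy_lambda) *
          (nests[src, ] - best_pos)
        cuckoo <- nests[src, ] + step
        f_c <- fitness(cuckoo)
        tgt <- if (src == 1L) sample.int(n, 1L) else src
        if (f_c > fit[tgt]) {
          nests[tgt, ] <- cuckoo
          fit[tgt] <- f_c
        }
      }
      # abandon the worst fraction, never the current best nest; abandoned
      # nests are rebuilt by a difference walk anchored at the best (quality)
      # solution, so the population keeps contracting around it
      m <- ceiling(cfg$p_abandon * n)
      if (m > 0L) {
        ord <- order(fit)                       # worst first
        cur_best <- which.max(fit)
        worst <- setdiff(ord, cur_best)[seq_len(min(m, n - 1L))]
        n_abandoned[gen] <- length(worst)
        for (i in worst) {
          p12 <- sample.int(n, 2L)
          cand <- nests[i, ] + stats::runif(d) *
            (nests[p12[1L], ] - nests[p12[2L], ])
          f_new <- fitness(cand)
          if (f_new > fit[i]) {          # greedy acceptance of the new nest
            nests[i, ] <- cand
            fit[i] <- f_new
          }
        }
      }
      bi <- which.max(fit)
      if (fit[bi] > best_fit) {
        best_fit <- fit[bi]
        best_pos <- nests[bi, ]
      }
      trace[gen + 1L] <- best_fit
    }
    list(best_position = best_pos, best_fitness = best_fit, trace = trace,
         n_abandoned = n_abandoned)
  })
}

#' Maximize a fitness with the bat algorithm
#'
#' Per bat and generation: a frequency `f_i ~ U(f_min, f_max)` drives the
#' velocity update `v <- v + (x - x_best) * f`, giving candidate `x + v`;
#' with probability `1 - r_i` the candidate is replaced by a local random walk
#' around the current best scaled by the mean loudness. A candidate is
#' accepted when `U(0,1) < A_i` and it strictly improves the bat's fitness;
#' acceptance decays the bat's loudness (`A <- alpha_loudness * A`) and raises
#' its pulse rate (`r <- r0 * (1 - exp(-gamma * t))`). The global best is
#' taken from accepted solutions only.
#'
#' @param fitness Function mapping a position vector to a scalar (maximized).
#' @param d Search dimension.
#' @param cfg A [ba_config()].
#' @param init_mean Optional initialization centre (see [run_pso()]).
#' @return List with `best_position`, `best_fitness`, best-so-far `trace`.
#' @export
run_ba <- function(fitness, d, cfg = ba_config(), init_mean = NULL) {
  d <- check_count(d, "d")
  with_seed(cfg$seed, {
    n <- cfg$n_bats
    x <- init_population(n, d, cfg$init_sd, init_mean)
    v <- matrix(0, n, d)
    fit <- apply(x, 1L, fitness)
    A <- rep(cfg$loudness, n)
    r <- rep(cfg$pulse_rate, n)
    best_i <- which.max(fit)
    best_pos <- x[best_i, ]
    best_fit <- fit[best_i]
    trace <- numeric(cfg$generations + 1L)
    trace[1L] <- best_fit
    for (gen in seq_len(cfg$generations)) {
      for (i in seq_len(n)) {
        f_i <- cfg$f_min + (cfg$f_max - cfg$f_min) * stats::runif(1L)
        v[i, ] <- v[i, ] + (x[i, ] - best_pos) * f_i
        cand <- x[i, ] + v[i, ]
        if (stats::runif(1L) > r[i]) {
          # local random walk around the best, shrinking with mean loudness
          cand <- best_pos + 0.1 * mean(A) * stats::rnorm(d)
        }
        f_cand <- fitness(cand)
        if (stats::runif(1L) < A[i] && f_cand > fit[i]) {
          x[i, ] <- cand
          fit[i] <- f_cand
          A[i] <- cfg$alpha_loudness * A[i]
          r[i] <- cfg$pulse_rate * (1 - exp(-cfg$gamma * gen))
          if (f_cand > best_fit) {
            best_fit <- f_cand
            best_pos <- cand
          }
        }
      }
      trace[gen + 1L] <- best_fit
    }
    list(best_position = best_pos, best_fitness = best_fit, trace = trace)
  })
}

#' Decode a continuous position into a feature mask
#'
#' Selects the `m` coordinates with the largest position values; ties are
#' broken toward the lowest index. The decoding is scale-invariant, so the
#' optimizers can roam unbounded positions.
#'
#' @param position Numeric vector.
#' @param m Number of features to select.
#' @return A `feature_mask`: list with logical `selected` and count `m`.
#' @export
mask_from_position <- function(position, m) {
  m <- check_count(m, "m")
  if (m > length(position)) abort_arg("`m` exceeds the position dimension")
  ord <- order(position, seq_along(position), decreasing = c(TRUE, FALSE),
               method = "radix")
  selected <- logical(length(position))
  selected[ord[seq_len(m)]] <- TRUE
  structure(list(selected = selected, m = m), class = "feature_mask")
}

#' Wrapper fitness of a feature mask
#'
#' Validation accuracy of a small fixed-budget DNN (one 8-unit hidden layer,
#' 5 epochs, no dropout) trained on the masked features of an inner stratified
#' 80/20 split. Deterministic under `split_seed`.
#'
#' @param mask A [mask_from_position()] result.
#' @param features Feature matrix (columns must match the mask dimension).
#' @param labels Binary labels; both classes must appear.
#' @param split_seed Seed controlling the inner split and classifier.
#' @return Validation accuracy in [0, 1].
#' @export
feature_fitness <- function(mask, features, labels, split_seed = 1L) {
  if (!inherits(mask, "feature_mask")) abort_arg("`mask` must be a feature_mask")
  features <- as.matrix(features)
  if (ncol(features) != length(mask$selected)) {
    abort_arg("mask dimension does not match the feature count")
  }
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) abort_arg("labels must contain both classes")
  sel <- features[, mask$selected, drop = FALSE]
  idx <- with_seed(split_seed, {
    val <- unlist(lapply(split(seq_along(y), y), function(ii) {
      take <- max(1L, round(0.2 * length(ii)))
      sample(ii, take)
    }))
    val
  })
  train_idx <- setdiff(seq_along(y), idx)
  cfg <- dnn_config(hidden_sizes = 8L, dropout_rate = 0, weight_decay = 1e-4,
                    epochs = 5L, fine_tune_epochs = 0L, batch_size = 32L,
                    learning_rate = 0.08, seed = split_seed)
  model <- train_dnn(sel[train_idx, , drop = FALSE], y[train_idx], cfg)
  pred <- predict_dnn(model, sel[idx, , drop = FALSE])$labels
  mean(pred == y[idx])
}

#' Select features with a swarm optimizer
#'
#' Runs the chosen optimizer over continuous positions of the feature
#' dimension, scoring candidate top-`m` masks with [feature_fitness()].
#' Fitness values are memoized per mask, so revisited masks cost nothing.
#' The population is seeded around standardized per-feature Welch
#' t-statistics, so the search starts from the filter-score mask and the
#' wrapper refines it.
#'
#' @param features Feature matrix (e.g. autoencoder bottleneck activations).
#' @param labels Binary labels.
#' @param m Number of features to keep.
#' @param method One of `"pso"`, `"cso"`, `"ba"`.
#' @param cfg Optimizer configuration matching `method` (defaults applied
#'   when `NULL`).
#' @param split_seed Seed for the wrapper fitness split.
#' @return List with the selected `mask`, the optimizer `result`, and the
#'   achieved `fitness`.
#' @export
select_features <- function(features, labels, m, method = c("pso", "cso", "ba"),
                            cfg = NULL, split_seed = 1L) {
  method <- match.arg(method)
  d <- ncol(features)
  m <- check_count(m, "m")
  if (m > d) abort_arg("`m` exceeds the feature dimension")
  if (is.null(cfg)) {
    cfg <- switch(method, pso = pso_config(), cso = cso_config(), ba = ba_config())
  }
  y01 <- as.integer(labels)
  tstat <- vapply(seq_len(d), function(j) {
    a <- features[y01 == 0L, j]
    b <- features[y01 == 1L, j]
    abs(mean(a) - mean(b)) /
      sqrt(stats::var(a) / length(a) + stats::var(b) / length(b) + 1e-12)
  }, numeric(1L))
  init_mean <- as.numeric(scale(tstat)[, 1L])
  if (anyNA(init_mean)) init_mean <- NULL   # constant scores: fall back
  cache <- new.env(parent = emptyenv())
  fit_fun <- function(position) {
    mask <- mask_from_position(position, m)
    key <- paste(which(mask$selected), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- feature_fitness(mask, features, labels, split_seed)
    assign(key, val, envir = cache)
    val
  }
  result <- switch(method,
                   pso = run_pso(fit_fun, d, cfg, init_mean = init_mean),
                   cso = run_cso(fit_fun, d, cfg, init_mean = init_mean),
                   ba = run_ba(fit_fun, d, cfg, init_mean = init_mean))
  list(mask = mask_from_position(result$best_position, m), result = result,
       fitness = result$best_fitness)
}
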