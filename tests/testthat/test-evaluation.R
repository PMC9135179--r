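tiny_profile <- function(seed) {
  # deliberately small configs so cross-validation tests run in seconds
  list(
    sae = sae_config(c(178L, 96L, 178L), iterations = 30L, learning_rate = 1e-3,
                     seed = seed),
    select = list(m = 48L,
                  pso = pso_config(n_particles = 5L, generations = 3L, seed = seed),
                  cso = cso_config(n_nests = 5L, generations = 3L, seed = seed),
                  ba = ba_config(n_bats = 5L, generations = 3L, seed = seed)),
    dnn = dnn_config(hidden_sizes = 16L, dropout_rate = 0, epochs = 40L,
                     fine_tune_epochs = 5L, batch_size = 16L,
                     learning_rate = 0.01, seed = seed),
    rbatq = rbatq_config(state_size = 6L, hidden = 6L, n_frames = 8L,
                         tree_depth = 1L, dropout_rate = 0, learning_rate = 0.02,
                         pretrain_epochs = 6L, epochs = 3L, seed = seed)
  )
}

make_pools <- function(n_per_set = 2L, sets = c("A", "E"), seed = 31L) {
  profiles <- bonn_class_profiles()
  pools <- list()
  for (i in seq_along(sets)) {
    prof <- if (sets[i] == "E") profiles$ictal else profiles$background
    recs <- generate_bonn_like(n_per_set, 4097L,
                               class_profiles = list(prof, prof),
                               seed = seed + i)[seq_len(n_per_set)]
    segs <- lapply(recs, function(r) {
      r$source_label <- sets[i]
      segment_recording(r, 23L)
    })
    pools[[sets[i]]] <- pool_segment_sets(segs)
  }
  pools
}

test_that("problem names parse to their pool structure and invalid names fail loudly", {
  p <- problem_spec("ACD-E")
  expect_identical(p$negative_sets, c("A", "C", "D"))
  expect_identical(p$positive_set, "E")
  expect_identical(problem_spec("schizophrenia")$negative_sets, "healthy")
  err <- tryCatch(problem_spec("Z-E"), condition = identity)
  expect_s3_class(err, "eegdeep_argument_error")
  expect_match(conditionMessage(err), "ABCD-E")    # names the valid problems
  expect_error(problem_spec("AA-E"), class = "eegdeep_argument_error")
})

test_that("compose_problem unions pools with correct labels and provenance", {
  pools <- make_pools(2L, c("A", "C", "D", "E"))
  ae <- compose_problem(pools, problem_spec("A-E"))
  expect_equal(n_segments(ae), 92L)
  expect_equal(sum(ae$labels == 0L), 46L)
  expect_equal(sum(ae$labels == 1L), 46L)
  acd <- compose_problem(pools, problem_spec("ACD-E"))
  expect_equal(sum(acd$labels == 0L), 138L)        # imbalance preserved
  expect_equal(sum(acd$labels == 1L), 46L)
  expect_identical(unique(acd$meta$source[acd$labels == 1L]), "E")
  expect_error(compose_problem(pools["A"], problem_spec("A-E")),
               class = "eegdeep_argument_error")
})

test_that("stratified folds partition the data with balanced class ratios", {
  labels <- rep(0:1, each = 1150L)
  folds <- kfold_split(2300L, 10L, labels, seed = 5L)
  expect_setequal(unique(folds), 1:10)
  expect_true(all(table(folds) == 230L))
  per_fold_pos <- tapply(labels, folds, sum)
  expect_true(all(per_fold_pos == 115L))
  expect_identical(folds, kfold_split(2300L, 10L, labels, seed = 5L))
  expect_false(identical(folds, kfold_split(2300L, 10L, labels, seed = 6L)))
  singles <- kfold_split(10L, 10L, rep(0L, 10L), seed = 1L)
  expect_setequal(singles, 1:10)
  expect_error(kfold_split(5L, 10L, rep(0L, 5L)), class = "eegdeep_argument_error")
})

test_that("confusion metrics follow their closed forms", {
  m <- confusion_metrics(structure(list(TP = 45L, TN = 40L, FP = 10L, FN = 5L),
                                   class = "confusion_counts"))
  expect_equal(unname(m["sensitivity"]), 90)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["accuracy"]), 85)
  expect_equal(unname(m["gdr"]), 90)               # GDR == sensitivity
  expect_equal(unname(m["error_rate"]), 15)
  perfect <- confusion_metrics(confusion_counts(c(0, 1, 1), c(0, 1, 1)))
  expect_equal(unname(perfect[c("sensitivity", "specificity", "accuracy", "error_rate")]),
               c(100, 100, 100, 0))
  degenerate <- confusion_metrics(confusion_counts(c(0, 0, 0), c(0, 1, 0)))
  expect_true(is.na(degenerate["sensitivity"]))
  expect_false(anyNA(degenerate[c("specificity", "accuracy", "error_rate")]))
  expect_error(confusion_metrics(confusion_counts(integer(0), integer(0))),
               class = "eegdeep_argument_error")
})

test_that("cross-validation conserves counts, bounds accuracy and reproduces under its seed", {
  pools <- make_pools(3L)
  data <- compose_problem(pools, problem_spec("A-E"))
  rep1 <- run_cv("sae_dnn", data, k = 5L, seed = 2L, profile = tiny_profile(2L))
  fold_sizes <- vapply(rep1$fold_counts,
                       function(cc) cc$TP + cc$FN + cc$TN + cc$FP, numeric(1L))
  expect_equal(sum(fold_sizes), n_segments(data))
  expect_lte(max(fold_sizes) - min(fold_sizes), 2L)
  expect_equal(sum(vapply(rep1$fold_counts, function(c) c$TP + c$FN, numeric(1L))),
               sum(data$labels))
  agg <- rep1$aggregate
  expect_gte(agg[["accuracy"]], min(agg[["sensitivity"]], agg[["specificity"]]) - 1e-9)
  expect_lte(agg[["accuracy"]], max(agg[["sensitivity"]], agg[["specificity"]]) + 1e-9)
  rep2 <- run_cv("sae_dnn", data, k = 5L, seed = 2L, profile = tiny_profile(2L))
  expect_identical(rep1$fold_metrics, rep2$fold_metrics)
  expect_error(run_cv("boosted_trees", data), class = "eegdeep_argument_error")
  single <- data; single$labels <- rep(0L, n_segments(single))
  expect_error(run_cv("sae_dnn", single), class = "eegdeep_argument_error")
})

test_that("corrupting the labels collapses held-out accuracy while honest labels stand", {
  pools <- make_pools(5L, seed = 77L)
  data <- compose_problem(pools, problem_spec("A-E"))
  honest <- run_cv("sae_dnn", data, k = 3L, seed = 4L, profile = tiny_profile(4L))
  scrambled <- data
  scrambled$labels <- eegdeep:::with_seed(15L, sample(data$labels))
  null_rep <- run_cv("sae_dnn", scrambled, k = 3L, seed = 4L, profile = tiny_profile(4L))
  expect_lt(abs(null_rep$aggregate[["accuracy"]] - 50), 12)
  expect_gt(honest$aggregate[["accuracy"]],
            null_rep$aggregate[["accuracy"]] + 20)
})

test_that("reports serialize to JSON with their aggregate metrics", {
  pools <- make_pools(2L)
  data <- compose_problem(pools, problem_spec("A-E"))
  rep1 <- run_cv("sae_dnn", data, k = 3L, seed = 1L, profile = tiny_profile(1L))
  path <- file.path(withr::local_tempdir(), "report.json")
  write_cv_report(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$aggregate$accuracy, rep1$aggregate[["accuracy"]])
  expect_equal(back$k, 3L)
  expect_length(back$fold_counts$TP, 3L)
})

test_that("agent reports carry per-fold episode-reward traces to a sidecar", {
  pools <- make_pools(2L)
  data <- compose_problem(pools, problem_spec("A-E"))
  rep1 <- run_cv("rbatq", data, k = 3L, seed = 1L, profile = tiny_profile(1L))
  expect_length(rep1$reward_traces, 3L)
  expect_true(all(lengths(rep1$reward_traces) == 3L))   # epochs per fold
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.json")
  write_cv_report(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$reward_trace_path, "reward_traces.json")
  traces <- jsonlite::read_json(file.path(dir, "reward_traces.json"),
                                simplifyVector = FALSE)
  expect_equal(unlist(traces[[1L]]), rep1$reward_traces[[1L]])
})
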