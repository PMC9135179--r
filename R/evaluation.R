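# Problem composition (A-E ... ABCD-E, schizophrenia), stratified 10-fold
# cross-validation, confusion-matrix metrics (sensitivity, specificity,
# accuracy, good detection rate, error rate) and the per-fold pipeline runner.

VALID_PIPELINES <- c("sae_dnn", "sasdl_pso", "sasdl_cso", "sasdl_ba", "rbatq")

#' Define a binary classification problem over labelled pools
#'
#' Canonical names look like `"A-E"` or `"ACD-E"`: the letters before the
#' dash are the negative (non-seizure) pools, the positive pool is `E`.
#' `"schizophrenia"` denotes healthy vs schizophrenia.
#'
#' @param name Canonical problem name.
#' @return A list with `negative_sets`, `positive_set`, `name`.
#' @export
problem_spec <- function(name) {
  if (identical(name, "schizophrenia")) {
    return(structure(list(negative_sets = "healthy",
                          positive_set = "schizophrenia",
                          name = name), class = "problem_spec"))
  }
  parts <- strsplit(name, "-", fixed = TRUE)[[1L]]
  neg <- if (length(parts) == 2L) strsplit(parts[1L], "")[[1L]] else character(0)
  if (length(parts) != 2L || parts[2L] != "E" || length(neg) < 1L ||
      !all(neg %in% c("A", "B", "C", "D")) || anyDuplicated(neg) > 0L) {
    abort_arg(sprintf(
      "unknown problem '%s'; valid: combinations of A-D vs E (e.g. 'A-E', 'ACD-E', 'ABCD-E') or 'schizophrenia'",
      name))
  }
  structure(list(negative_sets = neg, positive_set = "E", name = name),
            class = "problem_spec")
}

#' Compose a problem's segment set from labelled pools
#'
#' @param pools Named list of `eeg_segment_set` objects keyed by set label
#'   (e.g. `A`, `B`, ..., `E`).
#' @param spec A [problem_spec()].
#' @return The union set: negative pools labelled 0, the positive pool 1;
#'   per-segment source pools are recorded in `meta$source`.
#' @export
compose_problem <- function(pools, spec) {
  if (!inherits(spec, "problem_spec")) spec <- problem_spec(spec)
  wanted <- c(spec$negative_sets, spec$positive_set)
  missing <- setdiff(wanted, names(pools))
  if (length(missing) > 0L) {
    abort_arg(sprintf("missing pool(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(names(pools)) > 0L) abort_arg("pool names must be unique")
  parts <- lapply(wanted, function(nmp) {
    s <- pools[[nmp]]
    s$labels <- rep(as.integer(nmp == spec$positive_set), n_segments(s))
    s$meta$source <- rep(nmp, n_segments(s))
    s
  })
  out <- pool_segment_sets(parts)
  out$meta$problem <- spec$name
  out
}

#' Stratified k-fold assignment
#'
#' Within each class, indices are shuffled and dealt round-robin, so every
#' fold's class ratio is within one sample of the global ratio and the folds
#' partition `1..n`.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10).
#' @param labels Class labels (length `n`); a single class is allowed.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
kfold_split <- function(n, k = 10L, labels = rep(0L, n), seed = 1L) {
  n <- check_count(n, "n")
  k <- check_count(k, "k", min = 2L)
  if (k > n) abort_arg("`k` must not exceed `n`")
  if (length(labels) != n) abort_arg("`labels` length must equal n")
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      # rotate the starting fold per class so fold sizes stay balanced
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Confusion counts from truth and prediction
#'
#' @param truth,pred Binary 0/1 vectors.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) abort_arg("`truth` and `pred` lengths differ")
  structure(list(TP = sum(truth == 1L & pred == 1L),
                 TN = sum(truth == 0L & pred == 0L),
                 FP = sum(truth == 0L & pred == 1L),
                 FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

#' Metrics from confusion counts (percent)
#'
#' Sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, accuracy,
#' good detection rate (GDR, the fraction of true events detected, i.e.
#' sensitivity) and error rate `100 - accuracy`. A zero denominator marks
#' the affected metric `NA` (undefined) without poisoning the others.
#'
#' @param counts A [confusion_counts()] list.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`,
#'   `gdr`, `error_rate` (percent; `NA` = undefined).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0L) abort_arg("confusion counts are all zero")
  sens <- if (tp + fn > 0L) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / total
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    gdr = sens, error_rate = 100 - acc)
}

## ---- pipeline profiles -----------------------------------------------------

#' Built-in configuration profiles for the pipelines
#'
#' `"paper"` uses the published sizes (9000-unit bottleneck, 4500 selected
#' features, 2250/500 hidden units, LSTM state 250); `"test"` shrinks every
#' dimension roughly 30-fold so a full cross-validation completes in minutes
#' on one core.
#'
#' @param input_dim Width of a flattened segment.
#' @param profile `"test"` or `"paper"`.
#' @param seed Integer seed threaded into every component.
#' @return Named list of component configs (`sae`, `select`, `dnn`, `rbatq`).
#' @export
pipeline_profile <- function(input_dim, profile = c("test", "paper"), seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    list(
      sae = sae_config(c(input_dim, 9000L, input_dim), seed = seed),
      select = list(m = 4500L,
                    pso = pso_config(seed = seed),
                    cso = cso_config(seed = seed),
                    ba = ba_config(seed = seed)),
      dnn = dnn_config(seed = seed),
      rbatq = rbatq_config(seed = seed)
    )
  } else {
    bottleneck <- max(8L, min(128L, as.integer(floor(input_dim * 0.72))))
    list(
      sae = sae_config(c(input_dim, bottleneck, input_dim), iterations = 50L,
                       learning_rate = 1e-3, seed = seed),
      select = list(m = max(4L, as.integer(round(0.75 * bottleneck))),
                    pso = pso_config(n_particles = 12L, generations = 10L, seed = seed),
                    cso = cso_config(n_nests = 15L, generations = 12L, seed = seed),
                    ba = ba_config(n_bats = 15L, generations = 12L, seed = seed)),
      dnn = dnn_config(hidden_sizes = c(32L, 16L), dropout_rate = 0.1,
                       weight_decay = 1e-4, epochs = 85L, fine_tune_epochs = 20L,
                       batch_size = 32L, learning_rate = 0.005, seed = seed),
      rbatq = rbatq_config(state_size = 12L, hidden = 12L, n_frames = 8L,
                           tree_depth = 2L, dropout_rate = 0,
                           learning_rate = 0.02, batch_size = 25L,
                           max_norm = 3, pretrain_epochs = 40L, epochs = 10L,
                           seed = seed)
    )
  }
}

# Fit the requested pipeline on the training segments and predict the test
# segments. Every fitted component (autoencoder, mask, classifier, agent)
# sees training folds only.
fit_predict_pipeline <- function(pipeline, train_set, test_set, cfgs, fold_seed) {
  train_y <- train_set$labels
  if (pipeline == "rbatq") {
    cfg <- cfgs$rbatq
    cfg$seed <- fold_seed
    model <- train_rbatq(train_set, cfg)
    pred <- rbatq_predict(model, test_set)$labels
    attr(pred, "reward_trace") <- model$reward_trace
    return(pred)
  }
  sae_cfg <- cfgs$sae
  sae_cfg$seed <- fold_seed
  sae <- train_sae(train_set, sae_cfg)
  feats_train <- encode(sae, train_set)
  feats_test <- encode(sae, test_set)
  if (pipeline != "sae_dnn") {
    method <- sub("sasdl_", "", pipeline)
    sel_cfg <- cfgs$select[[method]]
    sel_cfg$seed <- fold_seed
    sel <- select_features(feats_train, train_y, m = cfgs$select$m,
                           method = method, cfg = sel_cfg,
                           split_seed = fold_seed)
    feats_train <- feats_train[, sel$mask$selected, drop = FALSE]
    feats_test <- feats_test[, sel$mask$selected, drop = FALSE]
  }
  dnn_cfg <- cfgs$dnn
  dnn_cfg$seed <- fold_seed
  model <- train_dnn(feats_train, train_y, dnn_cfg)
  predict_dnn(model, feats_test)$labels
}

#' Cross-validate a pipeline on a labelled segment set
#'
#' For each of `k` stratified folds, every fitted component (autoencoder,
#' swarm-selected mask, classifier, or the RBATQ state builders and agent) is
#' trained on the remaining folds only; the held-out fold is scored and the
#' aggregate is the unweighted mean of the per-fold metrics. Per-segment
#' z-score normalization is applied before any model sees data.
#'
#' @param pipeline One of `"sae_dnn"`, `"sasdl_pso"`, `"sasdl_cso"`,
#'   `"sasdl_ba"`, `"rbatq"`.
#' @param data A labelled `eeg_segment_set` containing both classes.
#' @param k Number of folds (default 10).
#' @param seed Integer seed (folds and per-fold component seeds).
#' @param profile Profile name passed to [pipeline_profile()], or a config
#'   list of the same shape.
#' @return A `cv_report`: per-fold counts and metrics, aggregate means, the
#'   configuration snapshot and seed.
#' @export
run_cv <- function(pipeline, data, k = 10L, seed = 1L, profile = "test") {
  if (!pipeline %in% VALID_PIPELINES) {
    abort_arg(sprintf("unknown pipeline '%s'; valid: %s", pipeline,
                      paste(VALID_PIPELINES, collapse = ", ")))
  }
  if (!inherits(data, "eeg_segment_set")) abort_arg("`data` must be an eeg_segment_set")
  if (length(unique(data$labels)) < 2L) abort_arg("`data` must contain both classes")
  data <- normalize_segments(data)
  n <- n_segments(data)
  folds <- kfold_split(n, k, data$labels, seed = derive_seed(seed, 0L))
  cfgs <- if (is.character(profile)) {
    pipeline_profile(flat_width(data), profile, seed = seed)
  } else profile
  fold_counts <- vector("list", k)
  reward_traces <- vector("list", k)
  fold_metrics <- matrix(0, k, 5L)
  colnames(fold_metrics) <- c("sensitivity", "specificity", "accuracy", "gdr",
                              "error_rate")
  for (fold in seq_len(k)) {
    train_set <- subset_segments(data, folds != fold)
    test_set <- subset_segments(data, folds == fold)
    pred <- fit_predict_pipeline(pipeline, train_set, test_set, cfgs,
                                 fold_seed = derive_seed(seed, fold))
    reward_traces[[fold]] <- attr(pred, "reward_trace")
    fold_counts[[fold]] <- confusion_counts(test_set$labels, as.integer(pred))
    fold_metrics[fold, ] <- confusion_metrics(fold_counts[[fold]])
  }
  structure(list(pipeline = pipeline, k = k, seed = seed,
                 fold_counts = fold_counts,
                 fold_metrics = as.data.frame(fold_metrics),
                 aggregate = colMeans(fold_metrics, na.rm = TRUE),
                 reward_traces = if (pipeline == "rbatq") reward_traces,
                 config = cfgs),
            class = "cv_report")
}

flat_width <- function(set) segment_length(set) * set$channel_count

subset_segments <- function(set, keep) {
  if (set$channel_count == 1L) {
    segs <- set$segments[keep, , drop = FALSE]
  } else {
    segs <- set$segments[keep, , , drop = FALSE]
  }
  meta <- set$meta
  if (!is.null(meta$source) && length(meta$source) == length(keep)) {
    meta$source <- meta$source[keep]
  }
  new_segment_set(segs, set$labels[keep], set$channel_count, meta)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> pipeline '%s', %d folds, seed %d\n",
              x$pipeline, x$k, x$seed))
  agg <- x$aggregate
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  GDR %.2f%%  error %.2f%%\n",
              agg["accuracy"], agg["sensitivity"], agg["specificity"],
              agg["gdr"], agg["error_rate"]))
  invisible(x)
}

#' Serialize a CV report to JSON
#'
#' For the agent pipeline the per-epoch episode-reward traces are written to
#' a sidecar file next to the report, referenced as `reward_trace_path`.
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  out <- list(pipeline = report$pipeline, k = report$k, seed = report$seed,
              aggregate = as.list(report$aggregate),
              fold_metrics = report$fold_metrics,
              fold_counts = lapply(report$fold_counts, unclass))
  if (!is.null(report$reward_traces)) {
    trace_path <- file.path(dirname(path), "reward_traces.json")
    jsonlite::write_json(report$reward_traces, trace_path, digits = NA)
    out$reward_trace_path <- basename(trace_path)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
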