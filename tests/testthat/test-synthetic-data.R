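test_that("Bonn-like generator returns the requested counts, lengths and labels", {
  recs <- generate_bonn_like(3L, 500L, seed = 7L)
  expect_length(recs, 6L)
  expect_true(all(vapply(recs, function(r) length(r$samples), integer(1L)) == 500L))
  labs <- vapply(recs, function(r) r$source_label, character(1L))
  expect_identical(labs, rep(c("synthetic-class0", "synthetic-class1"), each = 3L))
  expect_true(all(vapply(recs, function(r) r$sampling_rate_hz, numeric(1L)) == 173.61))
})

test_that("generator is bit-identical under a fixed seed and differs across seeds", {
  a <- generate_bonn_like(2L, 400L, seed = 7L)
  b <- generate_bonn_like(2L, 400L, seed = 7L)
  c <- generate_bonn_like(2L, 400L, seed = 8L)
  expect_identical(a, b)
  expect_false(identical(a[[1L]]$samples, c[[1L]]$samples))
})

test_that("seizure-like class carries more 3-5 Hz band power than background", {
  recs <- generate_bonn_like(10L, 4097L, seed = 1L)
  bp <- vapply(recs, function(r) band_power(r$samples, r$sampling_rate_hz, 3, 5),
               numeric(1L))
  labs <- vapply(recs, function(r) r$source_label, character(1L))
  expect_gt(mean(bp[labs == "synthetic-class1"]),
            mean(bp[labs == "synthetic-class0"]))
})

test_that("generator rejects non-positive counts and too-short recordings", {
  expect_error(generate_bonn_like(0L, 4097L), class = "eegdeep_argument_error")
  expect_error(generate_bonn_like(2L, 10L), class = "eegdeep_argument_error")
})

test_that("segment_recording applies floor division and drops the remainder", {
  rec <- new_recording(seq_len(4097L), source_label = "synthetic-class1")
  set <- segment_recording(rec, 23L)
  expect_equal(n_segments(set), 23L)
  expect_equal(segment_length(set), 178L)          # floor(4097 / 23)
  # concatenating the segments reproduces the first 23 * 178 samples exactly
  expect_identical(as.numeric(t(set$segments)), as.numeric(seq_len(23L * 178L)))
  expect_equal(set$meta$dropped_samples, 3L)
  expect_true(all(set$labels == 1L))

  exact <- segment_recording(new_recording(1:10), 10L)
  expect_equal(dim(exact$segments), c(10L, 1L))
  expect_equal(exact$meta$dropped_samples, 0L)

  expect_error(segment_recording(new_recording(1:5), 6L),
               class = "eegdeep_argument_error")
})

test_that("100 recordings x 23 chunks pool into 2300 segments", {
  recs <- generate_bonn_like(50L, 4097L, seed = 2L)
  pool <- pool_segment_sets(lapply(recs, segment_recording, n_chunks = 23L))
  expect_equal(n_segments(pool), 2300L)
  expect_equal(sum(pool$labels == 0L), 1150L)
  expect_equal(sum(pool$labels == 1L), 1150L)
})

test_that("a trivial band-power threshold separates the default classes well above chance", {
  pool <- normalize_segments(small_pool(15L, seed = 5L))
  bp <- apply(pool$segments, 1L, band_power, fs = 173.61, lo = 2, hi = 7)
  acc <- mean((bp > stats::median(bp)) == (pool$labels == 1L))
  expect_gt(acc, 0.8)
  # label-permuted copy sits at chance
  set.seed(11)
  perm <- sample(pool$labels)
  acc_perm <- mean((bp > stats::median(bp)) == (perm == 1L))
  expect_lt(abs(acc_perm - 0.5), 0.08)
})

test_that("multichannel generator honours shapes, seeds and the 1-channel degenerate case", {
  set <- generate_multichannel_like(1L, segment_length = 300L, n_segments = 5L,
                                    n_channels = 4L, seed = 1L)
  expect_equal(dim(set$segments), c(10L, 300L, 4L))
  expect_identical(set$labels, rep(0:1, each = 5L))
  set2 <- generate_multichannel_like(1L, segment_length = 300L, n_segments = 5L,
                                     n_channels = 4L, seed = 2L)
  expect_equal(dim(set2$segments), dim(set$segments))
  expect_false(identical(set$segments, set2$segments))
  one <- generate_multichannel_like(1L, segment_length = 200L, n_segments = 3L,
                                    n_channels = 1L, seed = 1L)
  expect_true(is.matrix(one$segments))
  expect_equal(dim(one$segments), c(6L, 200L))
  expect_error(generate_multichannel_like(0L), class = "eegdeep_argument_error")
})

test_that("multichannel classes differ in cross-channel covariance", {
  set <- generate_multichannel_like(1L, segment_length = 500L, n_segments = 8L,
                                    n_channels = 3L, seed = 4L)
  cov_of <- function(i) stats::cov(set$segments[i, , ])
  c0 <- Reduce(`+`, lapply(which(set$labels == 0L), cov_of)) / 8
  c1 <- Reduce(`+`, lapply(which(set$labels == 1L), cov_of)) / 8
  expect_gt(norm(c0 - c1, "F") / norm(c0, "F"), 0.1)
})

test_that("segment sets validate labels and finiteness", {
  m <- matrix(1:6, 2L, 3L)
  expect_error(new_segment_set(m, c(0L, 1L, 0L)), class = "eegdeep_argument_error")
  expect_error(new_segment_set(m, c(0L, 2L)), class = "eegdeep_argument_error")
  m[1L, 1L] <- NaN
  expect_error(new_segment_set(m, c(0L, 1L)), class = "eegdeep_argument_error")
})

test_that("segment-set bundles round-trip through disk", {
  pool <- small_pool(2L)
  dir <- withr::local_tempdir()
  save_segment_set(pool, dir)
  back <- load_segment_set(dir)
  expect_equal(back$segments, pool$segments)
  expect_identical(back$labels, pool$labels)
  expect_equal(back$channel_count, pool$channel_count)
})

test_that("per-segment normalization centres and scales every segment", {
  pool <- normalize_segments(small_pool(2L))
  expect_lt(max(abs(rowMeans(pool$segments))), 1e-10)
  rms <- sqrt(rowMeans(pool$segments^2))
  expect_lt(max(abs(rms - 1)), 1e-10)
})
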