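# Synthetic EEG generator: Bonn-style single-channel recordings and
# multichannel segment tensors with class-dependent structure, plus the
# chunking step that turns recordings into fixed-length labelled segments.

#' Construct a single-channel EEG recording
#'
#' @param samples Numeric vector of signal samples (microvolt-scale units).
#' @param sampling_rate_hz Positive sampling rate in Hz. Defaults to 173.61,
#'   the rate of the classic 100-recording epilepsy benchmark sets A-E.
#' @param source_label Provenance label: one of the benchmark set letters
#'   `"A"`..`"E"`, `"healthy"`, `"schizophrenia"`, or `"synthetic-class0"` /
#'   `"synthetic-class1"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(samples, sampling_rate_hz = 173.61,
                          source_label = "synthetic-class0") {
  if (length(samples) < 1L || !is.numeric(samples)) {
    abort_arg("`samples` must be a non-empty numeric vector")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort_arg("`samples` must be finite and free of NA")
  }
  check_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         source_label = as.character(source_label)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %.2f Hz, source '%s'\n",
              length(x$samples), x$sampling_rate_hz, x$source_label))
  invisible(x)
}

# Binary class implied by a provenance label: seizure/schizophrenia-like
# sources are the positive class.
label_for_source <- function(source_label) {
  as.integer(source_label %in% c("E", "schizophrenia", "synthetic-class1",
                                 "ictal"))
}

#' Construct a labelled EEG segment set
#'
#' @param segments Numeric matrix (`n_segments x segment_length`) for
#'   single-channel data, or a 3-d array
#'   (`n_segments x segment_length x n_channels`) for multichannel data.
#' @param labels Integer vector in `{0, 1}`, one label per segment.
#' @param channel_count Number of channels per segment.
#' @param meta Free-form provenance list (source sets, seed, generator
#'   parameters).
#' @return An object of class `eeg_segment_set`.
#' @export
new_segment_set <- function(segments, labels, channel_count = 1L,
                            meta = list()) {
  channel_count <- check_count(channel_count, "channel_count")
  if (channel_count == 1L) {
    if (!is.matrix(segments)) abort_arg("`segments` must be a matrix when channel_count is 1")
    n <- nrow(segments)
  } else {
    if (length(dim(segments)) != 3L || dim(segments)[3L] != channel_count) {
      abort_arg("`segments` must be an n x length x channels array")
    }
    n <- dim(segments)[1L]
  }
  if (length(labels) != n) abort_arg("`labels` length must match the number of segments")
  if (!all(labels %in% c(0L, 1L))) abort_arg("`labels` must be 0/1")
  if (anyNA(segments) || any(!is.finite(segments))) {
    abort_arg("`segments` must be finite and free of NA")
  }
  structure(
    list(segments = segments, labels = as.integer(labels),
         channel_count = channel_count, meta = meta),
    class = "eeg_segment_set"
  )
}

#' @export
print.eeg_segment_set <- function(x, ...) {
  n <- n_segments(x)
  cat(sprintf("<eeg_segment_set> %d segments x %d samples x %d channel(s); %d positive\n",
              n, segment_length(x), x$channel_count, sum(x$labels)))
  invisible(x)
}

#' @rdname new_segment_set
#' @param x An `eeg_segment_set`.
#' @export
n_segments <- function(x) {
  if (x$channel_count == 1L) nrow(x$segments) else dim(x$segments)[1L]
}

#' @rdname new_segment_set
#' @export
segment_length <- function(x) {
  if (x$channel_count == 1L) ncol(x$segments) else dim(x$segments)[2L]
}

# Default spectral/temporal class profiles: background is AR(2)-filtered
# Gaussian noise at unit variance with a broad alpha-like spectral peak near
# 10 Hz; the seizure-like class adds Poisson-timed 3-5 Hz spike-wave bursts at
# 4x the background amplitude. Ictal discharge is quasi-continuous, so the
# default rate (3/s, ~1 s long, overlapping) leaves essentially no one-second
# segment of the seizure class without a discharge, emulating the strongly
# separable healthy-vs-ictal contrast of the classic benchmark sets.
#' Default class profiles for the Bonn-like generator
#'
#' @return A list with `background` and `ictal` profile lists.
#' @export
bonn_class_profiles <- function() {
  list(
    background = list(ar = c(1.72, -0.846), burst_rate_hz = 0,
                      burst_amp = 0, burst_freq = c(3, 5)),
    ictal = list(ar = c(1.72, -0.846), burst_rate_hz = 5,
                 burst_amp = 4, burst_freq = c(3, 5),
                 burst_dur_s = c(0.8, 1.2))
  )
}

# One AR(2) noise trace scaled to unit variance.
ar2_noise <- function(n, ar) {
  x <- as.numeric(stats::arima.sim(model = list(ar = ar), n = n))
  x / stats::sd(x)
}

# Spike-wave burst waveform: fundamental plus a sharpening harmonic under a
# Hann window, centred frequency drawn from the profile's band. `amp` is the
# burst's RMS amplitude relative to the unit-variance background.
spike_wave <- function(n_samp, freq_hz, fs, amp) {
  t <- seq_len(n_samp) / fs
  carrier <- sin(2 * pi * freq_hz * t) + 0.6 * sin(4 * pi * freq_hz * t + pi / 3)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_samp) / (n_samp + 1))
  shaped <- carrier * win
  rms <- sqrt(mean(shaped^2))
  if (rms < 1e-12) return(shaped)
  amp * shaped / rms
}

generate_recording_from_profile <- function(n, profile, fs) {
  x <- ar2_noise(n, profile$ar)
  if (profile$burst_rate_hz > 0) {
    dur_s <- n / fs
    n_bursts <- stats::rpois(1L, profile$burst_rate_hz * dur_s)
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        f <- stats::runif(1L, profile$burst_freq[1L], profile$burst_freq[2L])
        len <- round(stats::runif(1L, profile$burst_dur_s[1L],
                                  profile$burst_dur_s[2L]) * fs)
        start <- sample.int(n, 1L)
        idx <- start:min(n, start + len - 1L)
        x[idx] <- x[idx] + spike_wave(length(idx), f, fs, profile$burst_amp)
      }
    }
  }
  x
}

#' Generate Bonn-like single-channel EEG recordings
#'
#' Produces `2 * n_recordings_per_class` labelled recordings: class 0 is
#' band-limited AR(2) background noise, class 1 additionally carries
#' high-amplitude 3-5 Hz spike-wave bursts, so class identity is recoverable
#' from low-frequency band power.
#'
#' @param n_recordings_per_class Number of recordings per class.
#' @param recording_length Samples per recording (>= 46, i.e. at least two
#'   default-length chunks). Defaults to 4097 at 173.61 Hz (23.6 s).
#' @param class_profiles A two-profile list as returned by
#'   [bonn_class_profiles()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List of `eeg_recording` objects (class 0 first, then class 1).
#' @export
generate_bonn_like <- function(n_recordings_per_class, recording_length = 4097L,
                               class_profiles = bonn_class_profiles(),
                               seed = 1L) {
  n_recordings_per_class <- check_count(n_recordings_per_class, "n_recordings_per_class")
  recording_length <- check_count(recording_length, "recording_length", min = 46L)
  if (length(class_profiles) != 2L) abort_arg("`class_profiles` must hold two profiles")
  fs <- 173.61
  with_seed(seed, {
    recs <- vector("list", 2L * n_recordings_per_class)
    for (i in seq_len(n_recordings_per_class)) {
      recs[[i]] <- new_recording(
        generate_recording_from_profile(recording_length, class_profiles[[1L]], fs),
        fs, "synthetic-class0")
    }
    for (i in seq_len(n_recordings_per_class)) {
      recs[[n_recordings_per_class + i]] <- new_recording(
        generate_recording_from_profile(recording_length, class_profiles[[2L]], fs),
        fs, "synthetic-class1")
    }
    recs
  })
}

#' Generate a multichannel segment set with class-dependent covariance
#'
#' Emulates the layout of a 19-channel clinical dataset stored as a
#' `segments x segment_length x channels` tensor. Each class mixes independent
#' AR(2) sources through its own channel-mixing matrix, so the classes differ
#' in cross-channel covariance.
#'
#' @param n_subjects_per_class Subjects per class; each contributes
#'   `n_segments` segments.
#' @param segment_length Samples per segment (default 5000).
#' @param n_segments Segments per subject (default 45).
#' @param n_channels Channels (default 19; 1 degenerates to a single-channel
#'   matrix usable by the Bonn-style pipeline).
#' @param seed Integer seed.
#' @return An [new_segment_set()] object.
#' @export
generate_multichannel_like <- function(n_subjects_per_class = 1L,
                                       segment_length = 5000L,
                                       n_segments = 45L,
                                       n_channels = 19L,
                                       seed = 1L) {
  n_subjects_per_class <- check_count(n_subjects_per_class, "n_subjects_per_class")
  segment_length <- check_count(segment_length, "segment_length")
  n_segments <- check_count(n_segments, "n_segments")
  n_channels <- check_count(n_channels, "n_channels")
  n_total <- 2L * n_subjects_per_class * n_segments
  with_seed(seed, {
    # class-specific mixing matrices: shared base plus a class-1 rotation so
    # covariance (not marginal power) carries the class signal
    base <- diag(n_channels) + matrix(stats::rnorm(n_channels^2, sd = 0.15),
                                      n_channels)
    delta <- matrix(stats::rnorm(n_channels^2, sd = 0.45), n_channels)
    mixers <- list(base, base + delta)
    segs <- array(0, dim = c(n_total, segment_length, n_channels))
    labels <- integer(n_total)
    row <- 0L
    for (cls in 0:1) {
      for (subj in seq_len(n_subjects_per_class)) {
        for (s in seq_len(n_segments)) {
          src <- vapply(seq_len(n_channels),
                        function(ch) ar2_noise(segment_length, c(1.1, -0.45)),
                        numeric(segment_length))      # length x channels
          row <- row + 1L
          segs[row, , ] <- src %*% t(mixers[[cls + 1L]])
          labels[row] <- cls
        }
      }
    }
    if (n_channels == 1L) {
      segs <- matrix(segs, nrow = n_total, ncol = segment_length)
    }
    new_segment_set(segs, labels, channel_count = n_channels,
                    meta = list(generator = "multichannel_like", seed = seed,
                                n_subjects_per_class = n_subjects_per_class))
  })
}

#' Split a recording into equal-length contiguous segments
#'
#' A 4097-sample recording split into 23 chunks yields 23 segments of
#' `floor(4097 / 23) = 178` samples; the 3-sample remainder is dropped.
#'
#' @param rec An `eeg_recording`.
#' @param n_chunks Number of non-overlapping chunks.
#' @return An [new_segment_set()] with every segment inheriting the
#'   recording's class label.
#' @export
segment_recording <- function(rec, n_chunks = 23L) {
  if (!inherits(rec, "eeg_recording")) abort_arg("`rec` must be an eeg_recording")
  n_chunks <- check_count(n_chunks, "n_chunks")
  len_total <- length(rec$samples)
  if (n_chunks > len_total) abort_arg("`n_chunks` exceeds the recording length")
  seg_len <- len_total %/% n_chunks
  used <- rec$samples[seq_len(n_chunks * seg_len)]
  segs <- matrix(used, nrow = n_chunks, ncol = seg_len, byrow = TRUE)
  new_segment_set(segs, rep(label_for_source(rec$source_label), n_chunks),
                  meta = list(source = rec$source_label,
                              sampling_rate_hz = rec$sampling_rate_hz,
                              dropped_samples = len_total - n_chunks * seg_len))
}

#' Pool several segment sets into one
#'
#' @param sets List of `eeg_segment_set` objects with identical segment length
#'   and channel count.
#' @return A single pooled `eeg_segment_set`; per-segment provenance is kept
#'   in `meta$source`.
#' @export
pool_segment_sets <- function(sets) {
  if (length(sets) == 0L) abort_arg("`sets` must be non-empty")
  if (!all(vapply(sets, inherits, logical(1L), "eeg_segment_set"))) {
    abort_arg("all elements must be eeg_segment_set objects")
  }
  ch <- unique(vapply(sets, function(s) s$channel_count, integer(1L)))
  sl <- unique(vapply(sets, segment_length, integer(1L)))
  if (length(ch) != 1L || length(sl) != 1L) {
    abort_arg("segment sets must agree in segment length and channel count")
  }
  if (ch == 1L) {
    segs <- do.call(rbind, lapply(sets, function(s) s$segments))
  } else {
    n_tot <- sum(vapply(sets, n_segments, integer(1L)))
    segs <- array(0, dim = c(n_tot, sl, ch))
    at <- 0L
    for (s in sets) {
      n <- n_segments(s)
      segs[at + seq_len(n), , ] <- s$segments
      at <- at + n
    }
  }
  labels <- unlist(lapply(sets, function(s) s$labels))
  src <- unlist(lapply(sets, function(s) {
    sv <- s$meta$source %||% "unknown"
    if (length(sv) == n_segments(s)) sv else rep(sv[1L], n_segments(s))
  }))
  new_segment_set(segs, labels, channel_count = ch, meta = list(source = src))
}

#' Per-segment z-score normalization
#'
#' Removes within-segment mean and amplitude (per channel for multichannel
#' data) before any model sees the data.
#'
#' @param set An `eeg_segment_set`.
#' @return The normalized set.
#' @export
normalize_segments <- function(set) {
  if (!inherits(set, "eeg_segment_set")) abort_arg("`set` must be an eeg_segment_set")
  if (set$channel_count == 1L) {
    set$segments <- zscore_rows(set$segments)
  } else {
    for (ch in seq_len(set$channel_count)) {
      set$segments[, , ch] <- zscore_rows(set$segments[, , ch])
    }
  }
  set$meta$normalized <- TRUE
  set
}

# Flatten an eeg_segment_set to a plain feature matrix (channels concatenated).
segments_as_matrix <- function(set) {
  if (set$channel_count == 1L) return(set$segments)
  n <- n_segments(set)
  matrix(set$segments, nrow = n)
}

#' Save / load a segment set as a directory bundle
#'
#' The bundle holds raw little-endian doubles (`segments.bin`) plus a JSON
#' sidecar with dimensions, labels and generator metadata.
#'
#' @param set An `eeg_segment_set`.
#' @param dir Directory to create/overwrite.
#' @return `save_segment_set` returns `dir` invisibly; `load_segment_set`
#'   returns the reconstructed set.
#' @export
save_segment_set <- function(set, dir) {
  if (!inherits(set, "eeg_segment_set")) abort_arg("`set` must be an eeg_segment_set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- if (set$channel_count == 1L) dim(set$segments) else dim(set$segments)
  con <- file(file.path(dir, "segments.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(set$segments), con, size = 8L, endian = "little")
  sidecar <- list(schema_version = 1L, dims = as.integer(dims),
                  channel_count = set$channel_count, labels = set$labels,
                  meta = set$meta)
  jsonlite::write_json(sidecar, file.path(dir, "segments.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_segment_set
#' @export
load_segment_set <- function(dir) {
  bin <- file.path(dir, "segments.bin")
  side <- file.path(dir, "segments.json")
  if (!file.exists(bin) || !file.exists(side)) {
    abort_format(sprintf("'%s' is not a segment-set bundle", dir))
  }
  info <- jsonlite::read_json(side, simplifyVector = TRUE)
  dims <- as.integer(info$dims)
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = prod(dims), size = 8L, endian = "little")
  if (length(vals) != prod(dims)) abort_format("segment bundle is truncated")
  segs <- if (length(dims) == 2L) matrix(vals, dims[1L], dims[2L]) else array(vals, dims)
  meta <- as.list(info$meta %||% list())
  new_segment_set(segs, as.integer(info$labels),
                  channel_count = as.integer(info$channel_count), meta = meta)
}
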