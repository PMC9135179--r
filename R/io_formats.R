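# Readers for the plain-text single-channel benchmark format and a minimal
# subset of the European Data Format (EDF), plus lossless feature persistence.

#' Read a Bonn-style plain-text recording (one sample per line)
#'
#' Tolerates Windows/Unix line endings and trailing blank lines. The sampling
#' rate is fixed at 173.61 Hz, the rate of the source benchmark.
#'
#' @param path Path to the text file.
#' @param source_label Optional provenance label; by default inferred from the
#'   first character of the file name (`Z/O/N/F/S` map to sets `A/B/C/D/E`,
#'   the benchmark's file-prefix convention), else `"unknown"`.
#' @return An [new_recording()] object.
#' @export
read_bonn_text <- function(path, source_label = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  # trailing blank lines are tolerated; blank/garbage lines elsewhere are not
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) abort_format(sprintf("file '%s' is empty", path))
  vals <- suppressWarnings(as.numeric(trimws(lines)))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    abort_format(sprintf("file '%s': line %d ('%s') is not a number",
                         path, bad[1L], lines[bad[1L]]))
  }
  if (is.null(source_label)) {
    prefix <- toupper(substr(basename(path), 1L, 1L))
    map <- c(Z = "A", O = "B", N = "C", F = "D", S = "E")
    source_label <- if (prefix %in% names(map)) unname(map[prefix]) else "unknown"
  }
  new_recording(vals, sampling_rate_hz = 173.61, source_label = source_label)
}

## ---- minimal EDF subset ----------------------------------------------------
# Fixed-layout 256-byte main header + 256 bytes per signal, then int16
# little-endian data records. Only signals, rates and labels are surfaced; no
# EDF+ annotations.

read_ascii_field <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", n = nchars)))
}

#' Read a European Data Format (EDF) file
#'
#' Minimal reader for continuous EDF: returns one recording per channel with
#' the channel's sampling rate; the channel label is kept in `source_label`.
#'
#' @param path Path to the EDF file.
#' @return A list of [new_recording()] objects, one per channel.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file '%s' does not exist", path))
  sz <- file.size(path)
  if (sz < 256L) abort_format(sprintf("'%s': too short to hold an EDF header", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  version <- read_ascii_field(con, 8L)
  if (version != "0") abort_format(sprintf("'%s': unsupported EDF version '%s'", path, version))
  invisible(readBin(con, "raw", n = 80L + 80L + 8L + 8L))   # patient/recording/date/time
  header_bytes <- suppressWarnings(as.integer(read_ascii_field(con, 8L)))
  invisible(readBin(con, "raw", n = 44L))                   # reserved
  n_records <- suppressWarnings(as.integer(read_ascii_field(con, 8L)))
  duration <- suppressWarnings(as.numeric(read_ascii_field(con, 8L)))
  ns <- suppressWarnings(as.integer(read_ascii_field(con, 4L)))
  if (anyNA(c(header_bytes, n_records, duration, ns)) || ns < 1L ||
      n_records < 1L || duration <= 0) {
    abort_format(sprintf("'%s': malformed EDF header", path))
  }
  if (header_bytes != 256L * (ns + 1L) || sz < header_bytes) {
    abort_format(sprintf("'%s': EDF header size field is inconsistent", path))
  }
  read_per_signal <- function(nchars) {
    vapply(seq_len(ns), function(i) read_ascii_field(con, nchars), character(1L))
  }
  labels <- read_per_signal(16L)
  invisible(readBin(con, "raw", n = 80L * ns))              # transducer
  invisible(readBin(con, "raw", n = 8L * ns))               # physical dimension
  phys_min <- as.numeric(read_per_signal(8L))
  phys_max <- as.numeric(read_per_signal(8L))
  dig_min <- as.numeric(read_per_signal(8L))
  dig_max <- as.numeric(read_per_signal(8L))
  invisible(readBin(con, "raw", n = 80L * ns))              # prefiltering
  spr <- as.integer(read_per_signal(8L))
  invisible(readBin(con, "raw", n = 32L * ns))              # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) || any(spr < 1L) ||
      any(dig_max <= dig_min)) {
    abort_format(sprintf("'%s': malformed EDF signal headers", path))
  }
  expected <- header_bytes + 2 * n_records * sum(spr)
  if (sz < expected) {
    abort_format(sprintf("'%s': truncated EDF data (%d bytes, expected %d)",
                         path, sz, expected))
  }
  sig <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      sig[[i]][(rec - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  lapply(seq_len(ns), function(i) {
    new_recording(sig[[i]], sampling_rate_hz = spr[i] / duration,
                  source_label = labels[i])
  })
}

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write recordings to a minimal EDF file
#'
#' Counterpart of [read_edf()], mainly for fixtures and interchange. All
#' recordings must share the same length and sampling rate; samples are
#' quantized to the 16-bit EDF grid over each channel's physical range.
#'
#' @param recordings List of `eeg_recording` objects (one per channel).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recordings, path) {
  if (length(recordings) < 1L ||
      !all(vapply(recordings, inherits, logical(1L), "eeg_recording"))) {
    abort_arg("`recordings` must be a non-empty list of eeg_recording objects")
  }
  lens <- vapply(recordings, function(r) length(r$samples), integer(1L))
  rates <- vapply(recordings, function(r) r$sampling_rate_hz, numeric(1L))
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
    abort_arg("all channels must share one length and sampling rate")
  }
  ns <- length(recordings)
  n_samp <- lens[1L]
  duration <- n_samp / rates[1L]
  phys_min <- vapply(recordings, function(r) min(r$samples) - 1e-6, numeric(1L))
  phys_max <- vapply(recordings, function(r) max(r$samples) + 1e-6, numeric(1L))
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  put <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  put("0", 8L); put("synthetic patient", 80L); put("synthetic recording", 80L)
  put("01.01.26", 8L); put("00.00.00", 8L)
  put(256L * (ns + 1L), 8L); put("", 44L); put(1L, 8L)
  put(format(duration, digits = 7), 8L); put(ns, 4L)
  for (r in recordings) put(r$source_label, 16L)
  for (i in seq_len(ns)) put("", 80L)
  for (i in seq_len(ns)) put("uV", 8L)
  for (i in seq_len(ns)) put(format(phys_min[i], digits = 7), 8L)
  for (i in seq_len(ns)) put(format(phys_max[i], digits = 7), 8L)
  for (i in seq_len(ns)) put(dig_min, 8L)
  for (i in seq_len(ns)) put(dig_max, 8L)
  for (i in seq_len(ns)) put("", 80L)
  for (i in seq_len(ns)) put(n_samp, 8L)
  for (i in seq_len(ns)) put("", 32L)
  for (i in seq_len(ns)) {
    r <- recordings[[i]]
    dig <- round((r$samples - phys_min[i]) * (dig_max - dig_min) /
                   (phys_max[i] - phys_min[i]) + dig_min)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

## ---- feature persistence ---------------------------------------------------

#' Persist a feature matrix with labels
#'
#' Lossless round-trip: raw little-endian doubles plus a versioned JSON
#' sidecar holding dimensions and labels.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Vector with one entry per row.
#' @param dir Directory to create/overwrite.
#' @return `save_features` returns `dir` invisibly; `load_features` returns
#'   `list(features, labels)`.
#' @export
save_features <- function(features, labels, dir) {
  if (!is.matrix(features) || nrow(features) == 0L || ncol(features) == 0L) {
    abort_arg("`features` must be a non-empty matrix")
  }
  if (length(labels) != nrow(features)) {
    abort_arg("`labels` length must equal nrow(features)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "features.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(features), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(schema_version = 1L, dims = dim(features), labels = labels),
    file.path(dir, "features.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_features
#' @export
load_features <- function(dir) {
  bin <- file.path(dir, "features.bin")
  side <- file.path(dir, "features.json")
  if (!file.exists(bin) || !file.exists(side)) {
    abort_format(sprintf("'%s' is not a feature bundle", dir))
  }
  info <- jsonlite::read_json(side, simplifyVector = TRUE)
  dims <- as.integer(info$dims)
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = prod(dims), size = 8L, endian = "little")
  if (length(vals) != prod(dims)) abort_format("feature bundle is truncated")
  list(features = matrix(vals, dims[1L], dims[2L]), labels = info$labels)
}
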