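# WAV input/output, resampling, and assembly of labeled multi-channel
# recordings from per-position files plus a CSV manifest.

#' Construct an audio signal
#'
#' A single auscultation position's waveform: normalized amplitudes in
#' `[-1, 1]`, a sample rate in Hz, and a position tag.
#'
#' @param samples Numeric vector of amplitudes, all in `[-1, 1]`.
#' @param sample_rate Sample rate in Hz (positive integer).
#' @param position One of the 12 position codes in [LUNG_POSITIONS], or
#'   `"unknown"`.
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate`, `position`.
#' @export
audio_signal <- function(samples, sample_rate, position = "unknown") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("`samples` must lie in [-1, 1] (normalize before construction)", call. = FALSE)
  }
  sample_rate <- .scalar_num(sample_rate, "sample_rate", lo = 1)
  if (!identical(position, "unknown")) position <- canonical_position(position)
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate, position = position),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %d samples @ %g Hz (%.2f s), peak %.3f\n",
              x$position, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Construct a multi-channel recording
#'
#' Aligned per-position signals sharing one sample rate and length, with one
#' class label for the whole recording.
#'
#' @param channels Named list of [audio_signal()] objects; names are position
#'   codes and must be unique.
#' @param label Class label: one of `"normal"`, `"wheeze"`, `"fine_crackle"`.
#' @param subject_id Opaque subject identifier.
#' @param augmented Logical flag marking augmentation-derived variants so
#'   that data splits can quarantine them.
#' @return An object of class `mc_recording`.
#' @export
multi_channel_recording <- function(channels, label, subject_id, augmented = FALSE) {
  if (!is.list(channels) || length(channels) == 0L) {
    stop("`channels` must be a non-empty list of audio_signal objects", call. = FALSE)
  }
  pos <- canonical_position(names(channels))
  if (anyDuplicated(pos)) stop("duplicate positions in `channels`", call. = FALSE)
  names(channels) <- pos
  rates <- vapply(channels, function(s) s$sample_rate, 0)
  lens <- vapply(channels, function(s) length(s$samples), 0L)
  if (length(unique(rates)) != 1L) stop("all channels must share one sample rate", call. = FALSE)
  if (length(unique(lens)) != 1L) stop("all channels must share one sample count", call. = FALSE)
  channels <- channels[order_positions(pos)]
  structure(
    list(channels = channels, label = canonical_class(label),
         subject_id = as.character(subject_id), augmented = isTRUE(augmented)),
    class = "mc_recording"
  )
}

#' @export
print.mc_recording <- function(x, ...) {
  s1 <- x$channels[[1]]
  cat(sprintf("<mc_recording> subject %s [%s]%s: %d channel(s) {%s}, %.2f s @ %g Hz\n",
              x$subject_id, x$label, if (x$augmented) " (augmented)" else "",
              length(x$channels), paste(names(x$channels), collapse = ","),
              length(s1$samples) / s1$sample_rate, s1$sample_rate))
  invisible(x)
}

# ---- WAV --------------------------------------------------------------------

#' Read a mono PCM WAV file
#'
#' Supports 16-bit integer PCM and 32-bit IEEE-float RIFF/WAVE files.
#' Integer samples are scaled by `1/32768` so that full-scale +32767 maps to
#' just under +1.  Stereo and other multi-channel files are rejected rather
#' than down-mixed.
#'
#' @param path Path to the file.
#' @param position Optional position tag to attach.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, position = "unknown") {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path, call. = FALSE)
  if (fmt$n_channels != 1L) {
    stop(sprintf("only mono WAV is supported (file has %d channels): %s",
                 fmt$n_channels, path), call. = FALSE)
  }
  if (fmt$format == 1L && fmt$bits == 16L) {
    samples <- readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                       signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    samples <- readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format tag %d, %d bits): %s",
                 fmt$format, fmt$bits, path), call. = FALSE)
  }
  samples <- pmin(1, pmax(-1, samples))
  audio_signal(samples, fmt$sample_rate, position)
}

#' Write an audio signal as a mono WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return Invisibly, `path`.
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!bit_depth %in% c(16, 32)) stop("bit_depth must be 16 or 32", call. = FALSE)
  n <- length(signal$samples)
  fs <- as.integer(round(signal$sample_rate))
  bytes_per <- bit_depth %/% 8
  data_size <- n * bytes_per
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bit_depth == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16) {
    q <- as.integer(pmin(32767, pmax(-32768, round(signal$samples * 32768))))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(signal$samples), con, 4, endian = "little")
  }
  invisible(path)
}

#' Resample a signal with band-limited interpolation
#'
#' Duration is preserved to within one sample period.  A signal already at
#' the target rate is returned unchanged.
#'
#' @param signal An [audio_signal()].
#' @param target_rate Target sample rate in Hz.
#' @return An [audio_signal()] at `target_rate`.
#' @export
resample_audio <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  target_rate <- .scalar_num(target_rate, "target_rate", lo = 1)
  if (abs(target_rate - signal$sample_rate) < 1e-9) return(signal)
  fr <- .rational_approx(target_rate / signal$sample_rate)
  y <- signal::resample(signal$samples, fr[1], fr[2])
  n_out <- round(length(signal$samples) * target_rate / signal$sample_rate)
  y <- .fix_length(as.numeric(y), n_out)
  y <- pmin(1, pmax(-1, y))
  audio_signal(y, target_rate, signal$position)
}

# Continued-fraction rational approximation p/q of x with q <= max_den.
.rational_approx <- function(x, max_den = 1000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

# Trim from the end / zero-pad at the end to exactly n samples.
.fix_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

# ---- manifest ---------------------------------------------------------------

#' Read a recording manifest
#'
#' CSV with header `subject_id,position,path,label`; every
#' `(subject_id, position)` pair must be unique and labels must belong to the
#' 3-class vocabulary.
#'
#' @param path CSV file path.
#' @return A `data.frame` with canonicalized positions and labels.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' Validate (and canonicalize) a manifest data frame
#' @param df Data frame with columns `subject_id`, `position`, `path`, `label`.
#' @return The canonicalized data frame.
#' @export
validate_manifest <- function(df) {
  need <- c("subject_id", "position", "path", "label")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$position <- canonical_position(df$position)
  df$label <- canonical_class(df$label)
  key <- paste(df$subject_id, df$position)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, position) pairs in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  lab_per_subj <- tapply(df$label, df$subject_id, function(l) length(unique(l)))
  if (any(lab_per_subj > 1)) {
    stop("inconsistent labels within subject(s): ",
         paste(names(lab_per_subj)[lab_per_subj > 1], collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Write a manifest CSV
#' @param df Manifest data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(df, path) {
  utils::write.csv(validate_manifest(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a labeled multi-channel recording set
#'
#' Groups manifest rows by subject and returns only subjects that have all
#' requested positions.  Every channel is resampled to `sample_rate`, then
#' trimmed from the end or zero-padded at the end to exactly
#' `duration_s * sample_rate` samples.
#'
#' @param manifest Manifest data frame or CSV path.
#' @param positions Non-empty subset of [LUNG_POSITIONS].
#' @param duration_s Common duration in seconds (default 10).
#' @param sample_rate Common processing rate in Hz (default 4000).
#' @param base_dir Directory against which relative manifest paths are
#'   resolved.
#' @return List of [multi_channel_recording()] objects.  An empty result (no
#'   subject has all requested positions) raises a warning.
#' @export
load_recording_set <- function(manifest, positions, duration_s = 10,
                               sample_rate = 4000, base_dir = ".") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  if (length(positions) == 0L) stop("`positions` must be non-empty", call. = FALSE)
  positions <- order_positions(unique(canonical_position(positions)))
  n_target <- as.integer(round(duration_s * sample_rate))
  subjects <- split(manifest, manifest$subject_id)
  out <- list()
  for (sid in names(subjects)) {
    rows <- subjects[[sid]]
    if (!all(positions %in% rows$position)) next
    chans <- list()
    for (p in positions) {
      fp <- rows$path[rows$position == p]
      if (!file.exists(fp)) fp <- file.path(base_dir, fp)
      sig <- read_wav(fp, position = p)
      sig <- resample_audio(sig, sample_rate)
      chans[[p]] <- audio_signal(.fix_length(sig$samples, n_target), sample_rate, p)
    }
    out[[sid]] <- multi_channel_recording(chans, rows$label[1], sid)
  }
  if (length(out) == 0L) {
    warning("no subject in the manifest has all requested positions: ",
            paste(positions, collapse = ", "), call. = FALSE)
  }
  unname(out)
}
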