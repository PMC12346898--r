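# MFCC feature extraction and row-wise channel fusion into the fixed-size
# model input grid.

#' MFCC extraction parameters
#'
#' Defaults follow the pipeline's processing settings: 4 kHz sample rate,
#' 25 ms Hann window, 10 ms hop, 40 mel filters, and coefficients 1..13
#' retained (the 0th, overall-log-energy coefficient is excluded).  Frames
#' are taken without center padding, so
#' `n_frames = 1 + floor((N - window) / hop)`.
#'
#' @param sample_rate Sample rate in Hz.
#' @param window_ms Analysis window in ms.
#' @param hop_ms Hop in ms.
#' @param n_mels Number of triangular mel filters.
#' @param n_coeffs_kept Number of cepstral coefficients kept (indices
#'   `1..n_coeffs_kept`).
#' @param fft_size FFT length; default is the next power of two at or above
#'   the window length.
#' @param log_floor Additive floor inside the log.
#' @return An object of class `mfcc_params`.
#' @export
mfcc_params <- function(sample_rate = 4000, window_ms = 25, hop_ms = 10,
                        n_mels = 40, n_coeffs_kept = 13, fft_size = NULL,
                        log_floor = 1e-10) {
  window <- as.integer(round(sample_rate * window_ms / 1000))
  hop <- as.integer(round(sample_rate * hop_ms / 1000))
  if (is.null(fft_size)) fft_size <- 2^ceiling(log2(window))
  fft_size <- as.integer(fft_size)
  if (window > fft_size) stop("window must not exceed fft_size", call. = FALSE)
  if (n_coeffs_kept >= n_mels) stop("n_coeffs_kept must be < n_mels", call. = FALSE)
  structure(list(
    sample_rate = sample_rate, window_ms = window_ms, hop_ms = hop_ms,
    window = window, hop = hop, n_mels = as.integer(n_mels),
    n_coeffs_kept = as.integer(n_coeffs_kept), fft_size = fft_size,
    log_floor = log_floor
  ), class = "mfcc_params")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_mels` triangular filters with centers uniformly spaced on the mel
#' scale between 0 Hz and the Nyquist frequency, evaluated on the FFT bin
#' grid.
#'
#' @param params An [mfcc_params()].
#' @return An `n_mels` x `(fft_size/2 + 1)` non-negative matrix; each row is
#'   one filter.
#' @export
mel_filterbank <- function(params) {
  stopifnot(inherits(params, "mfcc_params"))
  n_bins <- params$fft_size %/% 2 + 1L
  freqs <- (seq_len(n_bins) - 1) * params$sample_rate / params$fft_size
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(params$sample_rate / 2),
                 length.out = params$n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, params$n_mels, n_bins)
  for (m in seq_len(params$n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "center_freqs") <- hz_pts[2:(params$n_mels + 1L)]
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in), rows k = 0..n_out-1.
.dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  j <- seq_len(n_in) - 1
  d <- sqrt(2 / n_in) * cos(outer(k, j + 0.5) * pi / n_in)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

#' Compute MFCCs
#'
#' Pipeline: non-centered framing (window/hop from `params`), Hann window,
#' power spectrum, triangular mel filterbank, `log(. + log_floor)`,
#' orthonormal DCT-II, keep coefficients `1..n_coeffs_kept`.  Because the
#' 0th coefficient is dropped, the output is invariant to global gain.
#'
#' @param signal An [audio_signal()] at `params$sample_rate` (resample
#'   first otherwise).
#' @param params An [mfcc_params()].
#' @return An object of class `mfcc_matrix`: list with `values`
#'   (`n_coeffs_kept` x `n_frames` matrix), `params`, and `position`.
#' @export
compute_mfcc <- function(signal, params = mfcc_params()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(params, "mfcc_params"))
  if (abs(signal$sample_rate - params$sample_rate) > 1e-6) {
    stop(sprintf("signal is at %g Hz; resample to %g Hz first",
                 signal$sample_rate, params$sample_rate), call. = FALSE)
  }
  x <- signal$samples
  n <- length(x)
  if (n < params$window) stop("signal shorter than one analysis window", call. = FALSE)
  n_frames <- 1L + (n - params$window) %/% params$hop
  starts <- (seq_len(n_frames) - 1L) * params$hop
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(params$window) - 1) / (params$window - 1))
  frames <- matrix(0, params$fft_size, n_frames)
  idx <- outer(seq_len(params$window), starts, "+")
  frames[seq_len(params$window), ] <- x[idx] * win
  spec <- stats::mvfft(frames)[seq_len(params$fft_size %/% 2 + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(params)
  mel_energy <- fb %*% power
  log_mel <- log(mel_energy + params$log_floor)
  dct <- .dct_matrix(params$n_coeffs_kept + 1L, params$n_mels)
  coeffs <- (dct %*% log_mel)[-1L, , drop = FALSE]   # drop the 0th coefficient
  structure(list(values = coeffs, params = params, position = signal$position),
            class = "mfcc_matrix")
}

#' Stack per-channel MFCC matrices row-wise
#'
#' Concatenates channel MFCC matrices along the coefficient (row) axis in
#' the canonical position order ([LUNG_POSITIONS]), independent of the
#' order in which the matrices are supplied.
#'
#' @param mfccs List of `mfcc_matrix` objects with distinct positions,
#'   equal frame counts, and equal parameters.
#' @param order Optional explicit position order; must cover exactly the
#'   provided positions.  Default: canonical order.
#' @return A `(n_coeffs_kept * n_channels)` x `n_frames` matrix with
#'   attribute `channel_order`.
#' @export
concatenate_channels <- function(mfccs, order = NULL) {
  stopifnot(length(mfccs) >= 1, all(vapply(mfccs, inherits, TRUE, "mfcc_matrix")))
  pos <- vapply(mfccs, function(m) m$position, "")
  if (anyDuplicated(pos)) stop("duplicate channel positions", call. = FALSE)
  nf <- vapply(mfccs, function(m) ncol(m$values), 0L)
  if (length(unique(nf)) != 1L) stop("frame-count mismatch across channels", call. = FALSE)
  p1 <- mfccs[[1]]$params
  same <- vapply(mfccs, function(m) identical(unclass(m$params), unclass(p1)), TRUE)
  if (!all(same)) stop("MFCC parameter mismatch across channels", call. = FALSE)
  if (is.null(order)) {
    order <- order_positions(pos)
  } else {
    order <- canonical_position(order)
    if (!setequal(order, pos) || length(order) != length(pos)) {
      stop("`order` must cover exactly the provided positions", call. = FALSE)
    }
  }
  stacked <- do.call(rbind, lapply(order, function(p) mfccs[[match(p, pos)]]$values))
  attr(stacked, "channel_order") <- order
  stacked
}

# Align-corners linear interpolation matrix mapping n_in points to n_out.
# A single-point axis is replicated.
.interp_matrix <- function(n_out, n_in) {
  if (n_in == 1) return(matrix(1, n_out, 1))
  if (n_out == n_in) return(diag(n_in))
  pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  lo <- pmin(floor(pos), n_in - 2)
  fr <- pos - lo
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), lo + 1)] <- 1 - fr
  m[cbind(seq_len(n_out), lo + 2)] <- m[cbind(seq_len(n_out), lo + 2)] + fr
  m
}

#' Deterministic bilinear resize of a numeric grid
#'
#' Separable align-corners linear interpolation; resizing to the input's
#' own shape is the identity.
#'
#' @param grid Numeric matrix.
#' @param out_shape Integer pair (rows, cols).
#' @return Resized matrix.
#' @export
bilinear_resize <- function(grid, out_shape) {
  stopifnot(is.matrix(grid), length(out_shape) == 2)
  r <- .interp_matrix(out_shape[1], nrow(grid))
  c_ <- .interp_matrix(out_shape[2], ncol(grid))
  r %*% grid %*% t(c_)
}

#' Convert a stacked feature grid to the fixed-size model input
#'
#' Bilinearly resizes the whole stacked grid to `shape` (default 128 x 350),
#' then standardizes the grid to zero mean and unit variance (a variance
#' floor maps constant grids to all zeros).
#'
#' @param grid Stacked numeric matrix (e.g. from [concatenate_channels()]).
#' @param shape Output shape, default `c(128, 350)`.
#' @return An object of class `model_input`: list with `grid` (matrix of
#'   exactly `shape`), `channel_order`, and `provenance` (the resize
#'   applied).
#' @export
to_model_input <- function(grid, shape = c(128, 350)) {
  if (!is.matrix(grid) || nrow(grid) == 0 || ncol(grid) == 0) {
    stop("`grid` must be a non-empty matrix", call. = FALSE)
  }
  if (nrow(grid) < 2 || ncol(grid) < 2) {
    stop("degenerate (single-row/column) grid cannot be resized", call. = FALSE)
  }
  resized <- bilinear_resize(grid, shape)
  mu <- mean(resized)
  sdv <- stats::sd(as.vector(resized))
  std <- if (!is.finite(sdv) || sdv < 1e-8) {
    matrix(0, shape[1], shape[2])
  } else {
    (resized - mu) / sdv
  }
  structure(list(
    grid = std,
    channel_order = attr(grid, "channel_order"),
    provenance = sprintf("bilinear %dx%d -> %dx%d; standardized",
                         nrow(grid), ncol(grid), shape[1], shape[2])
  ), class = "model_input")
}

#' Build the MFCC model input for one recording
#'
#' Computes per-channel MFCCs for the requested positions, stacks them
#' row-wise in canonical order, and resizes/standardizes to the model grid.
#'
#' @param recording A [multi_channel_recording()].
#' @param positions Positions to use; default all channels of the recording.
#' @param params An [mfcc_params()].
#' @param shape Model input shape.
#' @return A `model_input`.
#' @export
recording_to_input <- function(recording, positions = NULL,
                               params = mfcc_params(), shape = c(128, 350)) {
  stopifnot(inherits(recording, "mc_recording"))
  if (is.null(positions)) positions <- names(recording$channels)
  positions <- canonical_position(positions)
  missing <- setdiff(positions, names(recording$channels))
  if (length(missing)) {
    stop("recording lacks position(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mfccs <- lapply(positions, function(p) compute_mfcc(recording$channels[[p]], params))
  to_model_input(concatenate_channels(mfccs), shape)
}

#' Build the raw time-series model input for one recording
#'
#' For the time-series baseline variants: each channel is resampled to
#' `n_samples` points, channels become the columns of an
#' `n_samples x n_channels` grid, and the grid is resized/standardized to
#' the model shape.
#'
#' @param recording A [multi_channel_recording()].
#' @param positions Positions to use; default all channels.
#' @param n_samples Time-series grid length (default 12000).
#' @param shape Model input shape.
#' @return A `model_input`.
#' @export
recording_to_ts_input <- function(recording, positions = NULL,
                                  n_samples = 12000, shape = c(128, 350)) {
  stopifnot(inherits(recording, "mc_recording"))
  if (is.null(positions)) positions <- names(recording$channels)
  positions <- order_positions(canonical_position(positions))
  missing <- setdiff(positions, names(recording$channels))
  if (length(missing)) {
    stop("recording lacks position(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(positions, function(p) {
    sig <- recording$channels[[p]]
    target <- n_samples / (length(sig$samples) / sig$sample_rate)
    .fix_length(resample_audio(sig, target)$samples, n_samples)
  })
  grid <- do.call(cbind, cols)
  attr(grid, "channel_order") <- positions
  to_model_input(grid, shape)
}
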