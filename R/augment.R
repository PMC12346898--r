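# Augmentation suite: convex background-noise mixing, phase-vocoder time
# stretching and pitch shifting, Gaussian/masking noise, amplitude and
# circular time shifts, and the class-rebalancing policy.

#' Augmentation parameter ranges
#'
#' Ranges from which [rebalance()] draws per-variant transform parameters.
#' Each field is a length-2 `c(min, max)` range (degenerate ranges pin the
#' parameter).
#'
#' @param w Background mixing weight range, within `[0, 1]`.
#' @param stretch_factor Time-stretch factor range (> 0).
#' @param pitch_semitones Pitch shift range in semitones, within
#'   `[-12, 12]`.
#' @param gauss_sigma Gaussian noise amplitude range.
#' @param shift_ms Circular time-shift range in ms.
#' @param mask_fraction Masked-sample fraction range, within `[0, 1)`.
#' @param amplitude_gain Amplitude gain range (> 0).
#' @param p_apply Probability that each transform is applied to a given
#'   variant.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(w = c(0.05, 0.3),
                                stretch_factor = c(0.9, 1.1),
                                pitch_semitones = c(-2, 2),
                                gauss_sigma = c(0, 0.02),
                                shift_ms = c(-500, 500),
                                mask_fraction = c(0, 0.05),
                                amplitude_gain = c(0.8, 1.2),
                                p_apply = 0.5) {
  chk <- function(x, name, lo = -Inf, hi = Inf) {
    if (length(x) != 2 || x[1] > x[2] || x[1] < lo || x[2] > hi) {
      stop(sprintf("`%s` must be an ordered range within [%s, %s]", name, lo, hi),
           call. = FALSE)
    }
    as.numeric(x)
  }
  structure(list(
    w = chk(w, "w", 0, 1),
    stretch_factor = chk(stretch_factor, "stretch_factor", lo = 1e-6),
    pitch_semitones = chk(pitch_semitones, "pitch_semitones", -12, 12),
    gauss_sigma = chk(gauss_sigma, "gauss_sigma", 0),
    shift_ms = chk(shift_ms, "shift_ms"),
    mask_fraction = chk(mask_fraction, "mask_fraction", 0, 1 - 1e-9),
    amplitude_gain = chk(amplitude_gain, "amplitude_gain", lo = 1e-9),
    p_apply = .scalar_num(p_apply, "p_apply", 0, 1)
  ), class = "augmentation_config")
}

#' Mix background noise into a signal (convex combination)
#'
#' Computes `(1 - w) * i_in + w * i_noise` sample-wise, exactly.  With
#' `w = 0` the input is returned; with `w = 1` the noise is returned.
#'
#' @param i_in Input [audio_signal()].
#' @param i_noise Background-noise [audio_signal()] of equal length and rate.
#' @param w Mixing weight in `[0, 1]`.
#' @return The mixed [audio_signal()].
#' @export
mix_background <- function(i_in, i_noise, w) {
  stopifnot(inherits(i_in, "audio_signal"), inherits(i_noise, "audio_signal"))
  w <- .scalar_num(w, "w", 0, 1)
  if (length(i_in$samples) != length(i_noise$samples)) {
    stop("signal and noise must have equal lengths", call. = FALSE)
  }
  if (abs(i_in$sample_rate - i_noise$sample_rate) > 1e-9) {
    stop("signal and noise must share one sample rate", call. = FALSE)
  }
  audio_signal((1 - w) * i_in$samples + w * i_noise$samples,
               i_in$sample_rate, i_in$position)
}

# ---- phase vocoder ----------------------------------------------------------

# Short-time Fourier transform / inverse with periodic Hann window.
.stft <- function(x, nfft, hop) {
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  starts <- seq(1L, max(1L, length(x) - nfft + 1L), by = hop)
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * win, numeric(nfft))
  stats::mvfft(frames)
}

.istft <- function(S, nfft, hop, n_out) {
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  frames <- Re(stats::mvfft(S, inverse = TRUE)) / nfft
  nf <- ncol(frames)
  y <- numeric((nf - 1L) * hop + nfft)
  wsum <- numeric(length(y))
  for (j in seq_len(nf)) {
    idx <- (j - 1L) * hop + seq_len(nfft)
    y[idx] <- y[idx] + frames[, j] * win
    wsum[idx] <- wsum[idx] + win^2
  }
  y <- y / pmax(wsum, 1e-8)
  .fix_length(y, n_out)
}

#' Time-stretch a signal with a phase vocoder
#'
#' Changes duration without changing pitch.  The output has approximately
#' `length(x) / factor` samples: `factor > 1` shortens (speeds up),
#' `factor < 1` lengthens.
#'
#' @param signal An [audio_signal()].
#' @param factor Stretch factor (> 0).
#' @return The stretched [audio_signal()].
#' @export
time_stretch <- function(signal, factor) {
  stopifnot(inherits(signal, "audio_signal"))
  factor <- .scalar_num(factor, "factor", lo = 1e-9)
  if (abs(factor - 1) < 1e-12) return(signal)
  x <- signal$samples
  n_out <- as.integer(round(length(x) / factor))
  nfft <- 256L
  hop_s <- 64L                       # synthesis hop
  # analysis positions advance by hop_s * factor (possibly fractional)
  n_frames <- max(2L, (n_out - nfft) %/% hop_s + 1L)
  pos <- 1 + (seq_len(n_frames) - 1) * hop_s * factor
  xp <- c(x, numeric(nfft + as.integer(ceiling(hop_s * factor)) + 2L))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  omega <- 2 * pi * (seq_len(nfft) - 1) / nfft       # bin frequencies (rad/sample)
  S_out <- matrix(0 + 0i, nfft, n_frames)
  phase_acc <- numeric(nfft)
  prev_phase <- NULL
  for (j in seq_len(n_frames)) {
    p0 <- as.integer(floor(pos[j]))
    frame <- xp[p0:(p0 + nfft - 1L)] * win
    spec <- stats::fft(frame)
    mag <- Mod(spec); ph <- Arg(spec)
    if (is.null(prev_phase)) {
      phase_acc <- ph
    } else {
      dp <- ph - prev_phase - omega * (hop_s * factor)
      dp <- dp - 2 * pi * round(dp / (2 * pi))        # principal value
      true_freq <- omega + dp / (hop_s * factor)
      phase_acc <- phase_acc + true_freq * hop_s
    }
    prev_phase <- ph
    S_out[, j] <- mag * exp(1i * phase_acc)
  }
  y <- .istft(S_out, nfft, hop_s, n_out)
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audio_signal(y, signal$sample_rate, signal$position)
}

#' Pitch-shift a signal, preserving duration
#'
#' Shifts the spectrum by `2^(semitones/12)` using a phase-vocoder stretch
#' followed by band-limited resampling back to the original length.
#'
#' @param signal An [audio_signal()].
#' @param semitones Shift in semitones, `|semitones| <= 12`.
#' @return The shifted [audio_signal()] (same length as the input).
#' @export
pitch_shift <- function(signal, semitones) {
  stopifnot(inherits(signal, "audio_signal"))
  semitones <- .scalar_num(semitones, "semitones", -12, 12)
  if (abs(semitones) < 1e-12) return(signal)
  r <- 2^(semitones / 12)
  n <- length(signal$samples)
  stretched <- time_stretch(signal, 1 / r)            # length ~ n * r
  fr <- .rational_approx(1 / r)
  y <- as.numeric(signal::resample(stretched$samples, fr[1], fr[2]))
  y <- .fix_length(y, n)
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audio_signal(y, signal$sample_rate, signal$position)
}

#' Elementwise augmentation transforms
#'
#' `add_gaussian_noise()` adds seeded white Gaussian noise of standard
#' deviation `sigma`; `amplitude_shift()` scales by `gain`;
#' `time_shift()` rotates the signal circularly by `shift_ms`;
#' `mask_noise()` zeroes a seeded random subset of samples drawn without
#' replacement.  All four preserve length.
#'
#' @param signal An [audio_signal()].
#' @param sigma Noise standard deviation (>= 0).
#' @param gain Amplitude factor (> 0); output is clipped to `[-1, 1]`.
#' @param shift_ms Circular shift in milliseconds (positive delays).
#' @param mask_fraction Fraction of samples to zero, in `[0, 1)`.
#' @param seed Integer seed for the random draws.
#' @return The transformed [audio_signal()].
#' @name elementwise_transforms
NULL

#' @rdname elementwise_transforms
#' @export
add_gaussian_noise <- function(signal, sigma, seed = 1) {
  stopifnot(inherits(signal, "audio_signal"))
  sigma <- .scalar_num(sigma, "sigma", lo = 0)
  if (sigma == 0) return(signal)
  y <- signal$samples +
    withr::with_seed(seed, stats::rnorm(length(signal$samples), 0, sigma))
  audio_signal(pmin(1, pmax(-1, y)), signal$sample_rate, signal$position)
}

#' @rdname elementwise_transforms
#' @export
amplitude_shift <- function(signal, gain) {
  stopifnot(inherits(signal, "audio_signal"))
  gain <- .scalar_num(gain, "gain", lo = 1e-12)
  audio_signal(pmin(1, pmax(-1, signal$samples * gain)),
               signal$sample_rate, signal$position)
}

#' @rdname elementwise_transforms
#' @export
time_shift <- function(signal, shift_ms) {
  stopifnot(inherits(signal, "audio_signal"))
  shift_ms <- .scalar_num(shift_ms, "shift_ms")
  n <- length(signal$samples)
  k <- as.integer(round(shift_ms * signal$sample_rate / 1000)) %% n
  if (k == 0) return(signal)
  y <- c(signal$samples[(n - k + 1):n], signal$samples[1:(n - k)])
  audio_signal(y, signal$sample_rate, signal$position)
}

#' @rdname elementwise_transforms
#' @export
mask_noise <- function(signal, mask_fraction, seed = 1) {
  stopifnot(inherits(signal, "audio_signal"))
  mask_fraction <- .scalar_num(mask_fraction, "mask_fraction", 0, 1 - 1e-12)
  n <- length(signal$samples)
  m <- as.integer(round(n * mask_fraction))
  if (m == 0) return(signal)
  idx <- withr::with_seed(seed, sample.int(n, m))
  y <- signal$samples
  y[idx] <- 0
  audio_signal(y, signal$sample_rate, signal$position)
}

# ---- rebalancing ------------------------------------------------------------

#' Class-rebalancing augmentation
#'
#' For each recording of class `c`, produces `policy[[c]]` additional
#' augmented variants (originals are retained), mirroring the clinical
#' protocol of 30 extra wheeze and 4 extra fine-crackle copies per original.
#' Each variant draws one seeded set of transform parameters from
#' `config` and applies it identically to every channel of the recording,
#' so channel alignment is preserved.  Variants carry `augmented = TRUE` so
#' that data splits can quarantine them.
#'
#' @param dataset List of [multi_channel_recording()] objects.
#' @param policy Named list/vector mapping class to a non-negative integer
#'   multiplicity, e.g. `c(wheeze = 30, fine_crackle = 4)`.
#' @param config An [augmentation_config()] of parameter ranges.
#' @param seed Integer seed.
#' @param backgrounds Optional list of background [audio_signal()]s for the
#'   noise mixer; defaults to the three stylized ICU sources.
#' @return The augmented dataset (originals first, then variants).
#' @export
rebalance <- function(dataset, policy, config = augmentation_config(), seed = 1,
                      backgrounds = NULL) {
  if (length(dataset) == 0L) stop("`dataset` must be non-empty", call. = FALSE)
  stopifnot(inherits(config, "augmentation_config"))
  pol <- stats::setNames(rep(0L, length(SOUND_CLASSES)), SOUND_CLASSES)
  if (length(policy)) {
    nm <- canonical_class(names(policy))
    if (any(unlist(policy) < 0)) stop("multiplicities must be >= 0", call. = FALSE)
    pol[nm] <- as.integer(unlist(policy))
  }
  fs <- dataset[[1]]$channels[[1]]$sample_rate
  n <- length(dataset[[1]]$channels[[1]]$samples)
  if (is.null(backgrounds)) {
    backgrounds <- lapply(c("ventilation", "babble", "rustle"), function(ty)
      synthesize_background(ty, duration_s = n / fs, sample_rate = fs,
                            seed = derive_seed(seed, "bg", ty)))
  }
  out <- dataset
  for (ri in seq_along(dataset)) {
    rec <- dataset[[ri]]
    m <- pol[[rec$label]]
    if (m == 0) next
    for (v in seq_len(m)) {
      vseed <- derive_seed(seed, rec$subject_id, v)
      draw <- withr::with_seed(vseed, {
        u <- function(rg) stats::runif(1, rg[1], rg[2])
        list(
          apply = stats::runif(7) < config$p_apply,
          w = u(config$w), stretch = u(config$stretch_factor),
          pitch = u(config$pitch_semitones), sigma = u(config$gauss_sigma),
          shift = u(config$shift_ms), mask = u(config$mask_fraction),
          gain = u(config$amplitude_gain),
          bg = sample.int(length(backgrounds), 1)
        )
      })
      chans <- lapply(rec$channels, function(sig) {
        s <- sig
        if (draw$apply[1]) s <- mix_background(s, backgrounds[[draw$bg]], draw$w)
        if (draw$apply[2]) {
          s <- time_stretch(s, draw$stretch)
          s <- audio_signal(.fix_length(s$samples, length(sig$samples)),
                            s$sample_rate, s$position)
        }
        if (draw$apply[3]) s <- pitch_shift(s, draw$pitch)
        if (draw$apply[4]) s <- add_gaussian_noise(s, draw$sigma, derive_seed(vseed, "gauss"))
        if (draw$apply[5]) s <- time_shift(s, draw$shift)
        if (draw$apply[6]) s <- mask_noise(s, draw$mask, derive_seed(vseed, "mask"))
        if (draw$apply[7]) s <- amplitude_shift(s, draw$gain)
        s
      })
      out[[length(out) + 1L]] <- multi_channel_recording(
        chans, rec$label, sprintf("%s_aug%03d", rec$subject_id, v), augmented = TRUE
      )
    }
  }
  out
}
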