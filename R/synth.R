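# Seeded synthetic multi-channel lung-sound simulator.
#
# The generator emulates the statistical structure the classification
# pipeline assumes: three classes (normal / wheeze / fine crackle) riding on
# a periodic breath envelope, simultaneous multi-position channels sharing
# one acoustic source with per-channel attenuation, delay and spectral tilt,
# independent sensor noise, and optional ICU-style background sources.

#' Specification of one synthetic recording
#'
#' @param label Class label (`"normal"`, `"wheeze"`, `"fine_crackle"`).
#' @param breath_rate Breathing rate in cycles/min.
#' @param crackle_density Expected crackle bursts per inspiration (0 for
#'   non-crackle classes).
#' @param wheeze_freq Tonal wheeze frequency in Hz (0 for non-wheeze classes).
#' @param base_noise_band Passband (low, high) in Hz of the broadband breath
#'   noise.
#' @param snr_db Signal-to-sensor-noise ratio per channel in dB (`Inf`
#'   disables sensor noise).
#' @param channel_gains Optional per-position gain factors (recycled);
#'   `NULL` uses a geometric 0.9^k attenuation across channels.
#' @param channel_delays_ms Optional per-position delays in ms; `NULL` uses
#'   1.5 ms increments.
#' @param duration_s Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param wheeze_level Wheeze tone amplitude relative to the RMS of the
#'   breath noise.
#' @param crackle_level Crackle transient amplitude relative to the RMS of
#'   the breath noise.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(label, breath_rate = 15,
                           crackle_density = if (label == "fine_crackle") 8 else 0,
                           wheeze_freq = if (label == "wheeze") 400 else 0,
                           base_noise_band = c(100, 900), snr_db = 20,
                           channel_gains = NULL, channel_delays_ms = NULL,
                           duration_s = 10, sample_rate = 4000,
                           wheeze_level = 3, crackle_level = 12) {
  label <- canonical_class(label)
  .scalar_num(breath_rate, "breath_rate", lo = 1)
  .scalar_num(duration_s, "duration_s", lo = 1e-3)
  .scalar_num(sample_rate, "sample_rate", lo = 1)
  stopifnot(length(base_noise_band) == 2)
  if (!(base_noise_band[1] > 0 && base_noise_band[1] < base_noise_band[2] &&
        base_noise_band[2] < sample_rate / 2)) {
    stop("base_noise_band must satisfy 0 < low < high < sample_rate/2", call. = FALSE)
  }
  if (crackle_density < 0) stop("crackle_density must be >= 0", call. = FALSE)
  structure(list(
    label = label, breath_rate = breath_rate, crackle_density = crackle_density,
    wheeze_freq = wheeze_freq, base_noise_band = base_noise_band, snr_db = snr_db,
    channel_gains = channel_gains, channel_delays_ms = channel_delays_ms,
    duration_s = duration_s, sample_rate = sample_rate,
    wheeze_level = wheeze_level, crackle_level = crackle_level
  ), class = "synthetic_spec")
}

#' Synthesize a breath amplitude envelope
#'
#' Periodic at `breath_rate`, with a tall inspiratory bump, a shallower
#' expiratory bump, and inter-phase pauses; per-cycle amplitudes are
#' slightly jittered.  Values lie in `[0, 1]`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (deterministic output per seed).
#' @return Numeric vector of length `duration_s * sample_rate` with
#'   attributes `inspiration` (logical vector marking inspiratory samples)
#'   and `n_inspirations` (number of complete inspiratory phases).
#' @export
synthesize_breath_envelope <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration_s * fs))
  period <- 60 / spec$breath_rate
  n_cycles <- ceiling(spec$duration_s / period) + 1L
  amps <- withr::with_seed(seed, stats::runif(n_cycles, 0.85, 1))
  t <- (seq_len(n) - 1) / fs
  cyc <- floor(t / period)
  ph <- (t / period) - cyc             # phase in [0, 1)
  env <- numeric(n)
  insp <- ph < 0.40                    # inspiration: first 40% of the cycle
  exph <- ph >= 0.45 & ph < 0.80       # expiration: 45%..80%
  env[insp] <- sin(pi * ph[insp] / 0.40)
  env[exph] <- 0.6 * sin(pi * (ph[exph] - 0.45) / 0.35)
  env <- env * amps[cyc + 1L]
  env <- pmin(1, pmax(0, env))
  n_insp <- sum(diff(c(FALSE, insp)) == 1L)
  attr(env, "inspiration") <- insp
  attr(env, "n_inspirations") <- n_insp
  env
}

# Band-pass filter via 4th-order Butterworth, zero phase.
.bandpass <- function(x, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Shared source split into the broadband base and the class cue so that the
# multi-channel generator can gate cues per position (complementary mode).
.synth_components <- function(spec, seed) {
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration_s * fs))
  env <- synthesize_breath_envelope(spec, derive_seed(seed, "env"))
  base <- withr::with_seed(derive_seed(seed, "base"), stats::rnorm(n))
  base <- .bandpass(base, spec$base_noise_band, fs) * env
  base_rms <- .rms(base[env > 0.1])
  if (!is.finite(base_rms) || base_rms == 0) base_rms <- .rms(base) + 1e-12
  wheeze <- numeric(n)
  crackle <- numeric(n)
  if (spec$label == "wheeze" && spec$wheeze_freq > 0) {
    t <- (seq_len(n) - 1) / fs
    phi <- withr::with_seed(derive_seed(seed, "wheeze"), stats::runif(1, 0, 2 * pi))
    wheeze <- spec$wheeze_level * base_rms * sin(2 * pi * spec$wheeze_freq * t + phi) * env
  }
  if (spec$label == "fine_crackle" && spec$crackle_density > 0) {
    insp <- attr(env, "inspiration")
    segs <- .runs(insp)
    crackle <- withr::with_seed(derive_seed(seed, "crackle"), {
      ck <- numeric(n)
      for (sg in segs) {
        m <- stats::rpois(1, spec$crackle_density)
        if (m == 0) next
        starts <- sort(stats::runif(m, sg[1], max(sg[1], sg[2] - 80)))
        for (s0 in starts) {
          f0 <- stats::runif(1, 200, 1000)
          len <- min(64L, n - as.integer(s0))   # 16 ms at 4 kHz
          if (len < 8L) next
          tt <- (seq_len(len) - 1) / fs
          burst <- exp(-tt / 0.003) * sin(2 * pi * f0 * tt)
          idx <- as.integer(s0) + seq_len(len) - 1L
          ck[idx] <- ck[idx] + spec$crackle_level * base_rms * burst
        }
      }
      ck
    })
  }
  list(base = base, wheeze = wheeze, crackle = crackle, envelope = env,
       n_inspirations = attr(env, "n_inspirations"))
}

# Runs of TRUE in a logical vector as list of c(start, end).
.runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

#' Synthesize a single-position source signal
#'
#' Normal recordings are breath-envelope-modulated band-passed noise; fine
#' crackle adds Poisson-placed short (\eqn{\le} 20 ms) damped-oscillation
#' transients during inspiratory phases; wheeze adds a continuous
#' envelope-modulated sinusoid at `wheeze_freq`.  Output is peak-normalized
#' to 0.9.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param position Position tag for the returned signal.
#' @return An [audio_signal()].
#' @export
synthesize_source <- function(spec, seed = 1, position = "unknown") {
  comp <- .synth_components(spec, seed)
  x <- comp$base + comp$wheeze + comp$crackle
  x <- 0.9 * x / max(abs(x))
  audio_signal(x, spec$sample_rate, position)
}

#' Synthesize a multi-channel recording from one shared source
#'
#' All channels derive from one source via per-channel gain, delay, and a
#' position-dependent first-order low-pass tilt (applied zero-phase), plus
#' independent Gaussian sensor noise at `snr_db`.
#'
#' `cue_mode` controls how class cues are distributed over positions:
#' `"shared"` places the full source on every channel; `"complementary"`
#' gates the wheeze tone onto upper-lobe positions only and crackle bursts
#' onto non-upper positions only, so no single channel carries evidence for
#' both adventitious classes; `"duplicated"` copies one channel verbatim to
#' every position (negative control: no complementary information).
#'
#' @param spec A [synthetic_spec()].
#' @param positions Character vector of position codes (non-empty).
#' @param seed Integer seed.
#' @param subject_id Subject identifier for the returned recording.
#' @param cue_mode One of `"shared"`, `"complementary"`, `"duplicated"`.
#' @return A [multi_channel_recording()].
#' @export
synthesize_recording <- function(spec, positions, seed = 1, subject_id = "S1",
                                 cue_mode = c("shared", "complementary", "duplicated")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cue_mode <- match.arg(cue_mode)
  if (length(positions) == 0L) stop("`positions` must be non-empty", call. = FALSE)
  positions <- canonical_position(positions)
  if (anyDuplicated(positions)) stop("duplicate positions", call. = FALSE)
  fs <- spec$sample_rate
  nc <- length(positions)
  comp <- .synth_components(spec, seed)
  gains <- spec$channel_gains
  delays <- spec$channel_delays_ms
  if (cue_mode == "duplicated") {
    gains <- rep(1, nc); delays <- rep(0, nc)
  } else {
    if (is.null(gains)) gains <- 0.9^(seq_len(nc) - 1)
    if (is.null(delays)) delays <- 1.5 * (seq_len(nc) - 1)
    gains <- rep_len(gains, nc); delays <- rep_len(delays, nc)
  }
  peak <- max(abs(comp$base + comp$wheeze + comp$crackle))
  chans <- list()
  for (i in seq_len(nc)) {
    p <- positions[i]
    if (cue_mode == "complementary") {
      upper <- grepl("UL$", p)
      x <- comp$base + (if (upper) comp$wheeze else 0) + (if (!upper) comp$crackle else 0)
    } else {
      x <- comp$base + comp$wheeze + comp$crackle
    }
    x <- 0.9 * x / peak
    if (cue_mode != "duplicated") {
      # spectral tilt: deeper channels progressively low-passed (zero phase,
      # RMS-preserving so channel_gains control energy exactly)
      cutoff <- 1800 * 0.85^(i - 1)
      bf <- signal::butter(1, cutoff / (fs / 2), type = "low")
      r0 <- .rms(x)
      x <- as.numeric(signal::filtfilt(bf, x))
      x <- x * r0 / (.rms(x) + 1e-12)
      nd <- as.integer(round(delays[i] * fs / 1000))
      if (nd > 0) x <- c(numeric(nd), x)[seq_along(comp$base)]
      x <- gains[i] * x
    }
    if (is.finite(spec$snr_db)) {
      nseed <- if (cue_mode == "duplicated") derive_seed(seed, "noise") else derive_seed(seed, "noise", p)
      sigma <- (.rms(x) + 1e-12) / 10^(spec$snr_db / 20)
      x <- x + withr::with_seed(nseed, stats::rnorm(length(x), 0, sigma))
    }
    chans[[p]] <- audio_signal(pmin(1, pmax(-1, x)), fs, p)
  }
  multi_channel_recording(chans, spec$label, subject_id)
}

#' Specification of a synthetic cohort
#'
#' Default class proportions mirror the printed clinical counts
#' 1827 normal / 447 wheeze / 43 fine crackle.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param class_proportions Proportions over (normal, wheeze, fine_crackle);
#'   must sum to 1.
#' @param positions Positions recorded for every subject.
#' @param seed Cohort seed; per-subject seeds are derived deterministically.
#' @param snr_db Per-channel signal-to-noise ratio in dB.
#' @param cue_mode Channel cue distribution (see [synthesize_recording()]).
#' @param duration_s,sample_rate Recording geometry.
#' @param breath_rate_range,wheeze_freq_range,crackle_density_range Uniform
#'   ranges from which per-subject physiology is drawn.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        class_proportions = c(normal = 1827, wheeze = 447,
                                              fine_crackle = 43) / 2317,
                        positions = c("BRUL", "BLUL", "BLLL", "BRLL"),
                        seed = 1, snr_db = 20,
                        cue_mode = c("shared", "complementary", "duplicated"),
                        duration_s = 10, sample_rate = 4000,
                        breath_rate_range = c(12, 20),
                        wheeze_freq_range = c(250, 600),
                        crackle_density_range = c(5, 10)) {
  cue_mode <- match.arg(cue_mode)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(class_proportions) != 3 || abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must be 3 values summing to 1", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    class_proportions = as.numeric(class_proportions),
    positions = canonical_position(positions), seed = as.integer(seed),
    snr_db = snr_db, cue_mode = cue_mode, duration_s = duration_s,
    sample_rate = sample_rate, breath_rate_range = breath_rate_range,
    wheeze_freq_range = wheeze_freq_range,
    crackle_density_range = crackle_density_range
  ), class = "cohort_spec")
}

#' Synthesize a labeled cohort of multi-channel recordings
#'
#' Class counts follow `class_proportions` by largest-remainder rounding;
#' class assignment over subjects and all per-subject physiology are
#' deterministic functions of the cohort seed.
#'
#' @param cs A [cohort_spec()].
#' @param out_dir Optional directory; when given, per-channel WAV files and
#'   a `manifest.csv` are written there via the audio module.
#' @return List with `recordings` (list of [multi_channel_recording()]) and
#'   `manifest` (data frame).
#' @export
synthesize_cohort <- function(cs, out_dir = NULL) {
  stopifnot(inherits(cs, "cohort_spec"))
  n <- cs$n_subjects
  counts <- largest_remainder(n, cs$class_proportions)
  labels <- rep(SOUND_CLASSES, times = counts)
  labels <- labels[withr::with_seed(derive_seed(cs$seed, "assign"), sample.int(n))]
  ids <- sprintf("S%04d", seq_len(n))
  recordings <- vector("list", n)
  rows <- list()
  for (i in seq_len(n)) {
    sseed <- derive_seed(cs$seed, "subject", ids[i])
    draw <- withr::with_seed(sseed, list(
      br = stats::runif(1, cs$breath_rate_range[1], cs$breath_rate_range[2]),
      wf = stats::runif(1, cs$wheeze_freq_range[1], cs$wheeze_freq_range[2]),
      cd = stats::runif(1, cs$crackle_density_range[1], cs$crackle_density_range[2])
    ))
    spec <- synthetic_spec(
      labels[i], breath_rate = draw$br,
      crackle_density = if (labels[i] == "fine_crackle") draw$cd else 0,
      wheeze_freq = if (labels[i] == "wheeze") draw$wf else 0,
      snr_db = cs$snr_db, duration_s = cs$duration_s, sample_rate = cs$sample_rate
    )
    rec <- synthesize_recording(spec, cs$positions, seed = sseed,
                                subject_id = ids[i], cue_mode = cs$cue_mode)
    recordings[[i]] <- rec
    for (p in names(rec$channels)) {
      fp <- if (is.null(out_dir)) "" else file.path(out_dir, sprintf("%s_%s.wav", ids[i], p))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], position = p, path = fp, label = labels[i],
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in recordings) {
      for (p in names(rec$channels)) {
        write_wav(rec$channels[[p]],
                  file.path(out_dir, sprintf("%s_%s.wav", rec$subject_id, p)))
      }
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(recordings = recordings, manifest = manifest)
}

#' Synthesize an ICU-style background contamination signal
#'
#' Three stylized sources: `"ventilation"` (mains-like hum with harmonics
#' under low-passed rumble), `"babble"` (speech-band noise with syllabic
#' amplitude modulation), and `"rustle"` (sparse high-passed noise bursts).
#' Peak-normalized to 0.9; intended as the noise input of the background
#' mixer during augmentation.
#'
#' @param type Background type.
#' @param duration_s Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param seed Integer seed.
#' @return An [audio_signal()].
#' @export
synthesize_background <- function(type = c("ventilation", "babble", "rustle"),
                                  duration_s = 10, sample_rate = 4000, seed = 1) {
  type <- match.arg(type)
  fs <- sample_rate
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  x <- withr::with_seed(derive_seed(seed, "bg", type), {
    switch(type,
      ventilation = {
        hum <- sin(2 * pi * 120 * t) + 0.5 * sin(2 * pi * 240 * t + 1) +
          0.25 * sin(2 * pi * 360 * t + 2)
        bf <- signal::butter(2, 80 / (fs / 2), type = "low")
        hum + 2 * as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
      },
      babble = {
        bf <- signal::butter(4, c(120, 1200) / (fs / 2), type = "pass")
        am <- 0.5 + 0.5 * sin(2 * pi * 4 * t + stats::runif(1, 0, 2 * pi))
        as.numeric(signal::filtfilt(bf, stats::rnorm(n))) * am
      },
      rustle = {
        bf <- signal::butter(4, 800 / (fs / 2), type = "high")
        bursts <- numeric(n)
        m <- stats::rpois(1, duration_s)
        if (m > 0) {
          starts <- stats::runif(m, 1, n - 400)
          for (s0 in starts) {
            len <- as.integer(stats::runif(1, 100, 400))
            idx <- as.integer(s0) + seq_len(len) - 1L
            idx <- idx[idx <= n]
            w <- sin(pi * seq_along(idx) / length(idx))^2
            bursts[idx] <- bursts[idx] + w
          }
        }
        as.numeric(signal::filtfilt(bf, stats::rnorm(n))) * bursts
      }
    )
  })
  audio_signal(0.9 * x / max(abs(x)), fs)
}
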