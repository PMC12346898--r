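# Independent test oracles, deliberately written with naive loops and
# direct formulas so they share no code path with the package.

# Brute-force MFCC: direct DFT per frame, explicit triangle weights,
# log, naive DCT-II (orthonormal), keep coefficients 1..n_kept.
oracle_mfcc <- function(x, fs = 4000, window = 100, hop = 40, nfft = 128,
                        n_mels = 40, n_kept = 13, log_floor = 1e-10) {
  n_frames <- 1 + (length(x) - window) %/% hop
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1) / (window - 1))
  n_bins <- nfft / 2 + 1
  # explicit triangle filters on the mel axis
  m2hz <- function(m) 700 * (10^(m / 2595) - 1)
  hz2m <- function(f) 2595 * log10(1 + f / 700)
  pts <- m2hz(seq(hz2m(0), hz2m(fs / 2), length.out = n_mels + 2))
  freqs <- (seq_len(n_bins) - 1) * fs / nfft
  tri <- matrix(0, n_mels, n_bins)
  for (m in 1:n_mels) {
    for (b in 1:n_bins) {
      f <- freqs[b]
      if (f >= pts[m] && f <= pts[m + 1]) {
        tri[m, b] <- (f - pts[m]) / (pts[m + 1] - pts[m])
      } else if (f > pts[m + 1] && f <= pts[m + 2]) {
        tri[m, b] <- (pts[m + 2] - f) / (pts[m + 2] - pts[m + 1])
      }
    }
  }
  out <- matrix(0, n_kept, n_frames)
  for (fr in 1:n_frames) {
    seg <- numeric(nfft)
    seg[1:window] <- x[(fr - 1) * hop + 1:window] * hann
    # direct DFT
    power <- numeric(n_bins)
    for (b in 1:n_bins) {
      k <- b - 1
      re <- sum(seg * cos(-2 * pi * k * (seq_len(nfft) - 1) / nfft))
      im <- sum(seg * sin(-2 * pi * k * (seq_len(nfft) - 1) / nfft))
      power[b] <- re^2 + im^2
    }
    logmel <- log(as.vector(tri %*% power) + log_floor)
    # naive orthonormal DCT-II, coefficients 1..n_kept
    for (k in 1:n_kept) {
      out[k, fr] <- sqrt(2 / n_mels) *
        sum(logmel * cos(pi * k * (seq_len(n_mels) - 0.5) / n_mels))
    }
  }
  out
}

# Dominant-frequency oracle via plain periodogram.
oracle_peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[1:(n %/% 2)]
  sp[1] <- 0
  (which.max(sp) - 1) * fs / n
}

# Transient-count oracle: short-window peak amplitudes thresholded at
# median + 4 * MAD.
oracle_transient_count <- function(x, fs, win_ms = 10) {
  w <- as.integer(fs * win_ms / 1000)
  nwin <- length(x) %/% w
  peaks <- vapply(seq_len(nwin), function(i) max(abs(x[(i - 1) * w + 1:w])), 0)
  thr <- stats::median(peaks) + 4 * stats::mad(peaks)
  sum(peaks > thr)
}

# Simple energy/peak heuristic separating the three classes:
# strong narrow spectral peak -> wheeze; many amplitude transients ->
# fine crackle; otherwise normal.
oracle_classify <- function(sig) {
  ns <- asNamespace("auscultnet")
  x <- sig$samples
  fs <- sig$sample_rate
  w <- ns$welch_psd(x, fs, nfft = 1024)
  band <- w$freq >= 150 & w$freq <= 1100
  psd <- w$psd[band]
  tonality <- max(psd) / stats::median(psd)
  n_trans <- oracle_transient_count(x, fs)
  if (tonality > 60) "wheeze"
  else if (n_trans >= 4) "fine_crackle"
  else "normal"
}

# Explicit-loop one-vs-rest metrics from a KxK confusion matrix.
oracle_metrics <- function(cm) {
  K <- nrow(cm); total <- sum(cm)
  res <- list()
  for (k in 1:K) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in 1:K) for (j in 1:K) {
      if (i == k && j == k) tp <- tp + cm[i, j]
      else if (i != k && j == k) fp <- fp + cm[i, j]
      else if (i == k && j != k) fn <- fn + cm[i, j]
      else tn <- tn + cm[i, j]
    }
    acc <- (tp + tn) / total
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    res[[k]] <- c(accuracy = acc, precision = p, recall = r,
                  specificity = sp, f1 = f1)
  }
  do.call(rbind, res)
}

# Hand-rolled 2-D valid/padded convolution + residual add for one channel
# configuration (triple loop; no im2col).
oracle_conv2d <- function(x_hwc, w, k, stride, pad) {
  # x_hwc: H x W x Cin array; w: Cout x (k*k*Cin) with (dy,dx,c) ordering
  H <- dim(x_hwc)[1]; W <- dim(x_hwc)[2]; Cin <- dim(x_hwc)[3]
  Cout <- nrow(w)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    s <- 0
    for (c in 1:Cin) for (dy in 1:k) for (dx in 1:k) {
      hi <- (ho - 1) * stride - pad + dy
      wi <- (wo - 1) * stride - pad + dx
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        s <- s + x_hwc[hi, wi, c] * w[co, dy + k * (dx - 1) + k * k * (c - 1)]
      }
    }
    out[ho, wo, co] <- s
  }
  out
}

make_tone <- function(freq, fs = 4000, dur = 1, amp = 0.5, position = "unknown") {
  t <- (seq_len(round(fs * dur)) - 1) / fs
  auscultnet::audio_signal(amp * sin(2 * pi * freq * t), fs, position)
}

make_noise_signal <- function(n = 4000, fs = 4000, seed = 1, amp = 0.5) {
  x <- withr::with_seed(seed, stats::runif(n, -1, 1)) * amp
  auscultnet::audio_signal(x, fs)
}
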