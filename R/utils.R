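#' Canonical auscultation position vocabulary
#'
#' The 12 chest-wall auscultation positions: anterior (`F`) and posterior
#' (`B`) views of the right/left upper, mid, and lower lung fields.  The
#' vector order is the canonical channel order used throughout the package
#' when stacking per-position features: anterior before posterior; within a
#' view, upper before mid before lower; within a level, right before left.
#'
#' @format Character vector of length 12 (e.g. `"BRUL"` = back right upper
#'   lung).
#' @export
LUNG_POSITIONS <- c(
  "FRUL", "FLUL", "FRML", "FLML", "FRLL", "FLLL",
  "BRUL", "BLUL", "BRML", "BLML", "BRLL", "BLLL"
)

#' Class labels for the three-way respiratory-sound problem
#'
#' Integer codes follow the convention 0 = normal, 1 = wheeze,
#' 2 = fine crackle.
#'
#' @format Character vector of length 3.
#' @export
SOUND_CLASSES <- c("normal", "wheeze", "fine_crackle")

# ---- internal helpers -------------------------------------------------------

#' Derive a child seed from a base seed and a label
#'
#' Deterministic fan-out of one global seed into per-module / per-subject
#' seeds.  Polynomial string hash folded into the positive 32-bit range.
#'
#' @param seed Integer base seed.
#' @param ... Labels (characters or numbers) identifying the consumer.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer(h + 1)
}

# Validate a scalar: finite single number
.scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  as.numeric(x)
}

.rms <- function(x) sqrt(mean(x^2))

# Canonicalize a position code to the 12-token vocabulary; error otherwise.
canonical_position <- function(pos) {
  p <- toupper(trimws(pos))
  bad <- !(p %in% LUNG_POSITIONS)
  if (any(bad)) {
    stop("unknown auscultation position(s): ", paste(unique(pos[bad]), collapse = ", "),
         " (expected one of ", paste(LUNG_POSITIONS, collapse = ", "), ")", call. = FALSE)
  }
  p
}

# Order positions canonically
order_positions <- function(pos) pos[order(match(pos, LUNG_POSITIONS))]

canonical_class <- function(label) {
  l <- tolower(trimws(label))
  l[l %in% c("crackle", "fine crackle", "fine-crackle")] <- "fine_crackle"
  l[l %in% c("wheezing")] <- "wheeze"
  bad <- !(l %in% SOUND_CLASSES)
  if (any(bad)) {
    stop("label(s) outside the 3-class vocabulary {",
         paste(SOUND_CLASSES, collapse = ", "), "}: ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  l
}

# Largest-remainder apportionment of `n` items to `p` proportions.
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  q <- n * p
  k <- floor(q)
  r <- n - sum(k)
  if (r > 0) {
    extra <- order(q - k, decreasing = TRUE)[seq_len(r)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

# Welch power spectral density (Hann window, mean of segment periodograms).
# Returns list(freq, psd) with psd in power per Hz.  Used by the synthetic
# module's spectral summaries and the spectral test oracles.
welch_psd <- function(x, fs, nfft = 512, overlap = 0.5) {
  n <- length(x)
  if (n < nfft) nfft <- 2^floor(log2(n))
  hop <- max(1L, floor(nfft * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)  # periodic Hann
  starts <- seq(1L, n - nfft + 1L, by = hop)
  u <- sum(win^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * win
    sp <- stats::fft(seg)[seq_len(nfft %/% 2 + 1)]
    acc <- acc + (Mod(sp)^2) / (u * fs)
  }
  psd <- acc / length(starts)
  # one-sided scaling (all bins except DC/Nyquist counted twice)
  psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]
  list(freq = (seq_along(psd) - 1) * fs / nfft, psd = psd)
}

# Magnitude-squared coherence between x and y via Welch cross-spectra.
msc_coherence <- function(x, y, fs, nfft = 256, overlap = 0.5) {
  n <- min(length(x), length(y))
  hop <- max(1L, floor(nfft * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  starts <- seq(1L, n - nfft + 1L, by = hop)
  nb <- nfft %/% 2 + 1
  sxx <- syy <- numeric(nb)
  sxy <- complex(real = numeric(nb), imaginary = numeric(nb))
  for (s in starts) {
    fx <- stats::fft(x[s:(s + nfft - 1L)] * win)[seq_len(nb)]
    fy <- stats::fft(y[s:(s + nfft - 1L)] * win)[seq_len(nb)]
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  coh <- Mod(sxy)^2 / pmax(sxx * syy, .Machine$double.xmin)
  list(freq = (seq_len(nb) - 1) * fs / nfft, coherence = coh)
}
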