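---
title: "Multi-channel lung-sound classification: models, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel lung-sound classification: models, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chest auscultation records lung sounds at up to twelve standard chest-wall
positions (anterior/posterior × right/left × upper/mid/lower; e.g. `BRUL` =
back right upper lung). Adventitious sounds — brief, high-amplitude *fine
crackles* and sustained tonal *wheezes* — are superimposed on normal breath
noise and are clinically diagnostic. Because the chest transmits sound
position-dependently, recording several positions simultaneously captures
complementary evidence that a single sensor misses. `auscultnet` implements a
full pipeline for the three-class problem (normal / wheeze / fine crackle,
coded 0/1/2): multi-channel WAV ingestion, MFCC feature extraction, row-wise
channel fusion, a residual CNN–LSTM classifier, an ensemble training
protocol, one-vs-rest evaluation metrics, and a channel-ablation experiment
that quantifies the multi-channel advantage.

Clinical multi-channel auscultation corpora are access-restricted, so the
package ships a seeded synthetic simulator as a first-class module: every
test, demo, and experiment in the package runs on simulator output.

## Feature front end

MFCCs are computed at a 4 kHz processing rate with a 25 ms window (100
samples), 10 ms hop (40 samples), 40 triangular mel filters spanning
0–2000 Hz, and coefficients 1–13 retained; the 0th coefficient (overall log
energy) is excluded, which makes the features invariant to global gain.
Choices the front end fixes where the protocol leaves room:

* **Framing** is not center-padded: `n_frames = 1 + floor((N - window)/hop)`
  (998 frames for 10 s). This is the simplest convention and is pinned by
  tests.
* **FFT size** is 128 (next power of two ≥ 100), with a Hann window,
  orthonormal DCT-II, and a `1e-10` additive log floor.
* **Channel fusion** stacks the 13-row MFCC matrices of the recorded
  positions along the row axis in a fixed canonical order (anterior before
  posterior, upper→mid→lower, right before left), giving a `13·C × 998`
  grid.
* **Model input**: the stacked grid is bilinearly resized
  (align-corners, separable) to exactly 128 × 350 and standardized to zero
  mean and unit variance per grid. Resizing the *stacked* grid (rather than
  per-channel) is one consistent reading of a fixed 128 × 350 input layer;
  it preserves the relative row geometry of all channels. Standardization
  is an addition for optimization stability. A constant grid maps to all
  zeros via a variance floor.

The time-series baseline variants (`*_ts`) skip MFCCs: each channel is
resampled to 12 000 points, channels form the columns of a `12000 × C`
grid, and the same resize/standardization applies.

## Classifier

The backbone is a ResNet-18-style stack: a 7×7 stride-2 convolution, batch
normalization, ReLU, 3×3 stride-2 max pooling, then four residual stages of
two blocks, each block two 3×3 convolutions with batch norm and a skip
connection (`y = F(x, W) + x`; a 1×1 projection aligns the skip when stride
or width changes; the post-addition ReLU is a separate layer so the block
mapping itself satisfies the identity property exactly). Average pooling
collapses the frequency (row) axis only, leaving a per-column feature
sequence; the `cnn_lstm_*` variants feed that sequence to a single LSTM
layer (64 hidden units) and classify its final hidden state, while the
`cnn_*` variants flatten the sequence. The head is dropout (0.3), a fully
connected layer, and a 3-way softmax.

Stage widths default to (16, 32, 64, 128) — about 0.75 M parameters —
rather than the canonical (64, 128, 256, 512) ≈ 11 M: the protocol this
follows reports a ≈3.6 M-parameter model, so a narrowed stack is the
default and widths are configurable. The layer census is available from
`describe_model()`. Other choices the package fixes: argmax ties resolve
to the lowest class index; inference always disables dropout and uses
batch-norm running statistics; parameter initialization is He-normal
(uniform for the LSTM, with a +1 forget-gate bias) and fully seeded.

The network, backpropagation, and the rectified-Adam optimizer
(β₁ = 0.9, β₂ = 0.999, ε = 1e-6, with the variance-rectification term
falling back to momentum updates while ρ_t ≤ 4) are implemented in R on
top of BLAS: convolutions run as sparse im2col gathers followed by dense
GEMM. Correctness is established by unit tests against a hand-rolled
triple-loop convolution and by numerical gradient checks on the smooth
upper layers.

## Training protocol

Reference configuration: 50 epochs, batch size 20, categorical
cross-entropy, RAdam, learning rate decaying *linearly* from 1e-4 to 5e-5
(the protocol states only the range; the linear shape is a package
decision), three independent sessions with seeds `base + 1..3`, and
model selection by best validation loss (a package decision; last-epoch
weights are not used). "Ensemble" is read as averaging evaluation *metrics*
across sessions and reporting mean ± sd;
probability averaging is available via `train_ensemble(aggregate =
"probs")` as the alternative reading.

Data are split 70:15:15 (train/validation/test), stratified per class by
largest-remainder apportionment, with all recordings of one subject (and
all augmented variants of a recording) confined to one partition.
Augmentation is applied **after** the split, to the training partition
only: augmenting first and then splitting — the alternative ordering — lets near-duplicates of one recording land on both sides of
the train/test boundary, which inflates test scores. Both orders are
supported (`augment$order` in the pipeline config) so the original
ordering can be reproduced deliberately.

The rebalancing policy "n augmentations per class" is read as *n
additional augmented copies per original* (so 30 wheeze augmentations turn
each wheeze recording into 31 items). Each variant draws one seeded
parameter set — background-mix weight, stretch factor, pitch shift,
Gaussian σ, circular shift, mask fraction, gain, each applied with
probability 0.5 — and applies it identically to every channel, preserving
inter-channel alignment. The background mixer is the exact convex
combination `(1−w)·signal + w·noise`; time shifting is circular; masking
zeroes a without-replacement sample subset. Backgrounds are the three
stylized ICU sources described below.

## The synthetic cohort generator

Each subject is one shared acoustic source rendered to all requested
positions:

* **Breath envelope**: periodic at the subject's breathing rate (drawn
  uniformly from 12–20 cycles/min), with a tall inspiratory bump (40% of
  the cycle), a 0.6-height expiratory bump (45–80%), inter-phase pauses,
  and per-cycle amplitude jitter.
* **Normal**: envelope-modulated band-passed (100–900 Hz) Gaussian noise.
* **Wheeze**: adds an envelope-modulated sinusoid at the subject's wheeze
  frequency (drawn from 250–600 Hz) at 3× the breath-noise RMS — a strong
  continuous tonal cue (≥ 100 ms segments by construction).
* **Fine crackle**: adds Poisson-placed transients during inspiratory
  phases (expected 5–10 per inspiration per subject), each an
  exponentially damped sinusoid (center frequency uniform in 200–1000 Hz,
  τ = 3 ms, 16 ms duration) at 12× the breath-noise RMS. The amplitude was
  calibrated once so that a median + 4·MAD short-window peak detector
  recovers the planted Poisson counts; fine crackles are, physically,
  high-amplitude discontinuous spikes.
* **Channels**: per-position gain (default geometric 0.9ᵏ), delay (default
  1.5 ms increments), an RMS-preserving first-order low-pass tilt
  (zero-phase, cutoff shrinking with channel depth), and independent
  Gaussian sensor noise at the configured SNR (default 20 dB).
* **Cue modes**: `shared` places the whole source on every channel;
  `complementary` gates the wheeze tone onto upper-lobe positions and
  crackle bursts onto the others (no single channel sees evidence for both
  adventitious classes — the construction used by the channel-ablation
  benchmark); `duplicated` copies one channel verbatim to all positions
  (negative control: extra channels add no information).
* **Cohorts**: class counts follow the configured proportions by largest
  remainder; the default proportions 1827/447/43 ÷ 2317 mirror the
  clinical class imbalance of the motivating corpus. All per-subject draws
  derive deterministically from the cohort seed, so cohorts are
  bit-reproducible.

What the simulator does **not** model: airway acoustics and chest-wall
transfer functions, inter-subject anatomical variability, mixed or
transitional adventitious sounds, real ICU noise statistics, device
coloration. Tests passing on this cohort therefore demonstrate that the
pipeline's machinery is correct and that the classifier can exploit
class-discriminative and channel-complementary structure — not that any
particular clinical accuracy would be attained on real patients.

## Experiment scales used by the automated checks

The package's heavier properties run at reduced, fixed scales chosen as
the smallest sizes at which the effects are stable: a learnability check
trains the narrow (8, 16, 32, 64)×1-block model for 10 epochs (batch 20,
RAdam, lr 3e-3 → 1e-3) on a 300-recording single-position balanced cohort
at 30 dB SNR and must exceed 0.80 test accuracy against a 1/3 chance
level; the channel-ablation benchmark uses a 150-subject complementary-cue
cohort, 64 × 176 inputs, the (8, 16, 32, 64)×1 model, 12 epochs, and 3
sessions, comparing
the four-channel subset against single channels from each cue group, plus
the duplicated-channel negative control at the same settings. The higher
learning rate for these reduced runs compensates for the small number of
optimizer steps; the reference 1e-4 → 5e-5 schedule remains the default
for full-scale training.

## Known limitations

* Pure-R training is CPU-bound; full-scale (50-epoch, wide-model) runs are
  slow compared to GPU frameworks, though the architecture and protocol
  are identical.
* Layer counts depend on the counting convention; the package documents
  its own layer census via `describe_model()` rather than quoting a single
  number.
* Welch spectra, coherence, and the WAV reader/writer are minimal
  implementations sufficient for the package's formats (16-bit PCM,
  32-bit float mono WAV).
* The phase-vocoder time stretch introduces the usual transient smearing;
  crackle timing inside augmented variants is therefore approximate, which
  is acceptable for augmentation but would not be for clinical timing
  analysis.
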