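test_that("WAV round trip is exact to the quantization bound", {
  sig <- make_noise_signal(4000, seed = 42, amp = 0.97)
  f16 <- withr::local_tempfile(fileext = ".wav")
  f32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, f16, bit_depth = 16)
  write_wav(sig, f32, bit_depth = 32)
  r16 <- read_wav(f16)
  r32 <- read_wav(f32)
  expect_equal(r16$sample_rate, 4000)
  expect_lte(max(abs(r16$samples - sig$samples)), 2^-15)
  # 32-bit float WAV stores single precision
  expect_lte(max(abs(r32$samples - sig$samples)), 2^-23)
  # second round trip through 16-bit is bit-stable (idempotent quantization)
  f16b <- withr::local_tempfile(fileext = ".wav")
  write_wav(r16, f16b, bit_depth = 16)
  expect_identical(read_wav(f16b)$samples, r16$samples)
})

test_that("full-scale 16-bit PCM maps to ~1 and zeros stay zero", {
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L + 8L, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little"); writeBin(1L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(4000L, con, 4, endian = "little")
  writeBin(8000L, con, 4, endian = "little"); writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(8L, con, 4, endian = "little")
  writeBin(c(32767L, -32768L, 0L, 16384L), con, 2, endian = "little")
  close(con)
  sig <- read_wav(f)
  expect_equal(sig$samples[1], 32767 / 32768)
  expect_equal(sig$samples[2], -1)
  expect_equal(sig$samples[3], 0)
  expect_equal(sig$sample_rate, 4000)

  z <- audio_signal(numeric(4000) + 0, 4000)
  fz <- withr::local_tempfile(fileext = ".wav")
  write_wav(z, fz)
  expect_identical(read_wav(fz)$samples, numeric(4000))
})

test_that("read_wav raises distinct errors for missing/stereo/unsupported files", {
  expect_error(read_wav("does-not-exist.wav"), "not found")
  # hand-build a stereo file
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L + 4L, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little"); writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little"); writeBin(4000L, con, 4, endian = "little")
  writeBin(16000L, con, 4, endian = "little"); writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(4L, con, 4, endian = "little")
  writeBin(c(0L, 0L), con, 2, endian = "little")
  close(con)
  expect_error(read_wav(f), "mono")
  # 8-bit: unsupported encoding
  f2 <- withr::local_tempfile(fileext = ".wav")
  con <- file(f2, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L + 2L, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little"); writeBin(1L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(4000L, con, 4, endian = "little")
  writeBin(4000L, con, 4, endian = "little"); writeBin(1L, con, 2, endian = "little")
  writeBin(8L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(2L, con, 4, endian = "little")
  writeBin(as.raw(c(128, 128)), con)
  close(con)
  expect_error(read_wav(f2), "unsupported")
})

test_that("resampling preserves duration and tone frequency", {
  sig <- make_tone(440, fs = 8000, dur = 2)
  expect_identical(resample_audio(sig, 8000), sig)
  down <- resample_audio(sig, 4000)
  expect_equal(length(down$samples), 8000)
  expect_equal(down$sample_rate, 4000)
  f_peak <- oracle_peak_freq(down$samples, 4000)
  expect_lt(abs(f_peak - 440), 4000 / length(down$samples) + 1e-9)  # within 1 bin
  # non-integer ratio
  up <- resample_audio(make_tone(300, fs = 3000, dur = 1), 4000)
  expect_equal(length(up$samples), 4000)
  expect_lt(abs(oracle_peak_freq(up$samples, 4000) - 300), 2)
})

test_that("audio_signal and recording constructors enforce invariants", {
  expect_error(audio_signal(numeric(0), 4000), "non-empty")
  expect_error(audio_signal(c(0, 1.5), 4000), "\\[-1, 1\\]")
  expect_error(audio_signal(0.5, -1), "sample_rate")
  expect_error(audio_signal(0.5, 4000, "XXX"), "unknown auscultation position")
  s1 <- audio_signal(numeric(100), 4000, "BRUL")
  s2 <- audio_signal(numeric(100), 4000, "BLUL")
  s3 <- audio_signal(numeric(50), 4000, "BLLL")
  expect_error(multi_channel_recording(list(BRUL = s1, BLLL = s3), "normal", "A"),
               "sample count")
  rec <- multi_channel_recording(list(BLUL = s2, BRUL = s1), "Fine Crackle", "A")
  expect_identical(rec$label, "fine_crackle")
  # canonical channel ordering applied
  expect_identical(names(rec$channels), c("BRUL", "BLUL"))
  expect_error(multi_channel_recording(list(BRUL = s1), "rhonchi", "A"), "vocabulary")
})

test_that("load_recording_set groups by subject, pads/trims, never mixes subjects", {
  dir <- withr::local_tempdir()
  fs <- 4000
  # subject A: two positions with distinct constant-ish levels; subject B: one
  mk <- function(level, n) audio_signal(rep(level, n), fs)
  write_wav(mk(0.25, 2 * fs), file.path(dir, "A_BRUL.wav"))       # 2 s -> pad
  write_wav(mk(0.50, 3 * fs), file.path(dir, "A_BLUL.wav"))
  write_wav(mk(0.75, 2 * fs), file.path(dir, "B_BRUL.wav"))
  man <- data.frame(
    subject_id = c("A", "A", "B"),
    position = c("BRUL", "BLUL", "BRUL"),
    path = c("A_BRUL.wav", "A_BLUL.wav", "B_BRUL.wav"),
    label = c("normal", "normal", "wheeze")
  )
  recs <- load_recording_set(man, c("BRUL", "BLUL"), duration_s = 2.5,
                             sample_rate = fs, base_dir = dir)
  expect_length(recs, 1)
  expect_identical(recs[[1]]$subject_id, "A")
  ch <- recs[[1]]$channels
  expect_equal(length(ch$BRUL$samples), 10000)    # 2.5 s at 4 kHz
  # planted constants: channels belong to subject A only
  expect_equal(stats::median(ch$BRUL$samples), 0.25, tolerance = 1e-3)
  expect_equal(stats::median(ch$BLUL$samples), 0.50, tolerance = 1e-3)
  # 2 s file zero-padded at the end to 2.5 s
  expect_equal(ch$BRUL$samples[9000:10000], rep(0, 1001), tolerance = 1e-6)
  # 3 s file truncated from the end
  expect_equal(stats::median(ch$BLUL$samples[9000:10000]), 0.5, tolerance = 1e-3)

  expect_error(load_recording_set(man, character(0)), "non-empty")
  expect_warning(load_recording_set(man, c("BRUL", "BLUL", "BLLL"),
                                    sample_rate = fs, base_dir = dir),
                 "no subject")
})

test_that("manifests reject duplicates and out-of-vocabulary labels", {
  man <- data.frame(subject_id = c("A", "A"), position = c("BRUL", "BRUL"),
                    path = c("x.wav", "y.wav"), label = c("normal", "normal"))
  expect_error(validate_manifest(man), "duplicate")
  man2 <- data.frame(subject_id = "A", position = "BRUL", path = "x.wav",
                     label = "rhonchi")
  expect_error(validate_manifest(man2), "vocabulary")
  f <- withr::local_tempfile(fileext = ".csv")
  ok <- data.frame(subject_id = "A", position = "brul", path = "x.wav",
                   label = "Wheezing")
  write_manifest(ok, f)
  back <- read_manifest(f)
  expect_identical(back$position, "BRUL")
  expect_identical(back$label, "wheeze")
})
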