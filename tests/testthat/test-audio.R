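# Audio synthesis: clear speech, sine-wave speech, noise vocoding,
# amplitude equalization and WAV round-trips.

test_that("clear synthesis yields the exact concatenated duration", {
  spec <- fix_pool5()[1, ]
  a <- synthesize_clear(spec, fs = 22050, n_iterations = 3)
  expect_equal(length(a$samples), 231525) # 3 x 3.5 s x 22050
  expect_equal(a$variant, "clear")
  expect_equal(a$n_iterations, 3L)
  # concatenation: iterations are identical
  it <- matrix(a$samples, ncol = 3)
  expect_equal(it[, 1], it[, 2])
})

test_that("zero syllable envelope produces silence", {
  spec <- fix_pool5()[1, ]
  spec$syllable_env[[1]] <- spec$syllable_env[[1]] * 0
  a <- synthesize_clear(spec, n_iterations = 1)
  expect_equal(max(abs(a$samples)), 0)
})

test_that("clear-speech spectrum carries energy ridges at the formants", {
  spec <- fix_pool5()[2, ]
  a <- synthesize_clear(spec, n_iterations = 1)
  fs <- a$fs
  # short-time spectra at a few frame centers vs the known tracks
  for (tc in c(1, 2, 3)) {
    idx <- round(tc * fs) + seq_len(1024)
    seg <- a$samples[idx] * signal::hanning(1024)
    sp <- Mod(fft(seg))[1:512]
    fr <- (0:511) / 1024 * fs
    f_true <- spec$formant_freq[[1]][, round(tc * spec$ctrl_fs)]
    for (k in 1:3) {
      on_f <- max(sp[abs(fr - f_true[k]) < 120])
      # troughs midway between this formant and its neighbors
      off <- mean(c(
        max(sp[abs(fr - (f_true[k] - 250)) < 60]),
        max(sp[abs(fr - (f_true[k] + 250)) < 60])
      ))
      expect_gt(on_f, off)
    }
  }
})

test_that("sine-wave synthesis concentrates energy at the formant frequencies", {
  spec <- fix_pool5()[1, ]
  const_f <- c(500, 1500, 2500, 3500)
  spec$formant_freq[[1]][] <- matrix(const_f,
    nrow = 4,
    ncol = ncol(spec$formant_freq[[1]])
  )
  a <- sine_wave_synthesize(spec, n_iterations = 1)
  sp <- Mod(fft(a$samples))
  n <- length(a$samples)
  fr <- (seq_len(n %/% 2) - 1) / n * a$fs
  sp <- sp[seq_len(n %/% 2)]
  near_formant <- rowSums(sapply(const_f, function(f) abs(fr - f) < 30)) > 0
  expect_gt(min(sapply(const_f, function(f) max(sp[abs(fr - f) < 30]))),
    50 * max(sp[!near_formant & fr > 100]))
})

test_that("zero-amplitude tracks give silent sine-wave speech", {
  spec <- fix_pool5()[1, ]
  spec$formant_amp[[1]] <- spec$formant_amp[[1]] * 0
  a <- sine_wave_synthesize(spec, n_iterations = 1)
  expect_equal(max(abs(a$samples)), 0)
})

test_that("sine-wave speech lacks the harmonic stack between formants", {
  spec <- fix_pool5()[3, ]
  clear <- synthesize_clear(spec, n_iterations = 1)
  sws <- sine_wave_synthesize(spec, n_iterations = 1)
  band_energy <- function(a, lo, hi) {
    n <- length(a$samples)
    sp <- Mod(fft(a$samples))[seq_len(n %/% 2)]^2
    fr <- (seq_len(n %/% 2) - 1) / n * a$fs
    sum(sp[fr >= lo & fr <= hi]) / sum(sp)
  }
  # the gap between this sentence's F1 and F2 excursions: clear speech
  # fills it with source harmonics, SWS leaves it nearly empty
  freq <- spec$formant_freq[[1]]
  lo <- max(freq[1, ]) + 120
  hi <- min(freq[2, ]) - 120
  gap_clear <- band_energy(clear, lo, hi)
  gap_sws <- band_energy(sws, lo, hi)
  expect_gt(gap_clear, 10 * gap_sws)
})

test_that("noise vocoding preserves length and RMS, and silence maps to silence", {
  spec <- fix_pool5()[1, ]
  clear <- synthesize_clear(spec, n_iterations = 1)
  nvs <- noise_vocode(clear, n_bands = 7)
  expect_equal(length(nvs$samples), length(clear$samples))
  expect_equal(
    sqrt(mean(nvs$samples^2)), sqrt(mean(clear$samples^2)),
    tolerance = 1e-10
  )
  expect_equal(nvs$variant, "NVS")
  silent <- audio_stimulus(numeric(22050), 22050, "clear", sentence_id = 1L)
  expect_equal(max(abs(noise_vocode(silent)$samples)), 0)
  expect_error(noise_vocode(nvs), "clear")
  expect_error(noise_vocode(clear, n_bands = 1), "n_bands")
})

test_that("vocoding is reproducible for a given sentence", {
  spec <- fix_pool5()[1, ]
  clear <- synthesize_clear(spec, n_iterations = 1)
  expect_identical(noise_vocode(clear)$samples, noise_vocode(clear)$samples)
})

test_that("NVS preserves and SWS destroys the 2-8 Hz envelope structure", {
  # property over the pool: clear-NVS envelope correlation beats
  # clear-SWS on at least 90% of sentences
  rc <- env_corr_pool()
  expect_gte(mean(rc$r_nvs > rc$r_sws), 0.9)
  expect_true(all(rc$r_nvs >= 0.7))
})

test_that("amplitude equalization gives exactly equal RMS", {
  s1 <- audio_stimulus(rnorm(1000, sd = 0.1), 22050, "NVS")
  s2 <- audio_stimulus(rnorm(1000, sd = 0.2), 22050, "NVS")
  out <- equalize_amplitude(list(s1, s2), target_rms = 0.1)
  expect_equal(sqrt(mean(out[[1]]$samples^2)), 0.1, tolerance = 1e-12)
  expect_equal(sqrt(mean(out[[2]]$samples^2)), 0.1, tolerance = 1e-12)
  # shape preserved
  expect_equal(cor(out[[2]]$samples, s2$samples), 1)
  expect_error(
    equalize_amplitude(list(audio_stimulus(numeric(10), 22050, "NVS"))),
    "silent"
  )
})

test_that("equalized pool has max/min RMS ratio 1 within 1e-6", {
  set.seed(4)
  stimuli <- lapply(1:20, function(i) {
    audio_stimulus(rnorm(2000, sd = runif(1, 0.05, 0.5)), 22050, "NVS")
  })
  out <- equalize_amplitude(stimuli)
  r <- vapply(out, function(s) sqrt(mean(s$samples^2)), numeric(1))
  expect_lt(max(r) / min(r) - 1, 1e-6)
})

test_that("WAV files round-trip float samples", {
  x <- sin(2 * pi * 440 * (0:999) / 22050) * 0.4
  a <- audio_stimulus(x, 22050, "clear")
  path <- tempfile(fileext = ".wav")
  write_wav(a, path)
  back <- read_wav(path)
  expect_equal(back$fs, 22050)
  expect_equal(back$samples, x, tolerance = 1e-7)
  unlink(path)
})
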