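#' Construct an audio stimulus object
#'
#' A lightweight container for a sampled waveform plus the metadata the
#' pipeline needs: sampling rate, stimulus variant (`"clear"`, `"SWS"`,
#' `"NVS"` or `"training"`), sentence identity and number of concatenated
#' sentence iterations.
#'
#' @param samples Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param variant One of `"clear"`, `"SWS"`, `"NVS"`, `"training"`.
#' @param sentence_id Integer sentence identifier (`NA` for training audio).
#' @param n_iterations Number of concatenated iterations of the sentence.
#' @return An object of class `audio_stimulus`.
#' @export
audio_stimulus <- function(samples, fs, variant,
                           sentence_id = NA_integer_, n_iterations = 1L) {
  variant <- match.arg(variant, c("clear", "SWS", "NVS", "training"))
  structure(
    list(
      samples = as.numeric(samples), fs = fs, variant = variant,
      sentence_id = sentence_id, n_iterations = as.integer(n_iterations)
    ),
    class = "audio_stimulus"
  )
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf(
    "<audio_stimulus> %s, %.2f s @ %g Hz (sentence %s, %d iteration%s)\n",
    x$variant, length(x$samples) / x$fs, x$fs,
    ifelse(is.na(x$sentence_id), "-", x$sentence_id),
    x$n_iterations, ifelse(x$n_iterations > 1, "s", "")
  ))
  invisible(x)
}

# time-varying formant-shaping of a source signal by STFT multiplication.
# freq/amp are n_formants x n_ctrl trajectories at ctrl_fs.
formant_shape <- function(source, fs, freq, amp, ctrl_fs, bw = 90) {
  n <- length(source)
  win_len <- 1024L
  hop <- win_len %/% 2L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / win_len) # periodic Hann
  pad <- c(numeric(hop), source, numeric(win_len))
  out <- numeric(length(pad))
  fbin <- (seq_len(win_len) - 1) / win_len * fs
  fbin[fbin > fs / 2] <- fs - fbin[fbin > fs / 2]
  starts <- seq(1L, length(pad) - win_len, by = hop)
  tc <- (starts - 1 + win_len / 2 - hop) / fs # frame centers in source time
  idx_ctrl <- pmin(pmax(round(tc * ctrl_fs) + 1, 1), ncol(freq))
  for (i in seq_along(starts)) {
    s <- starts[i]
    fr <- freq[, idx_ctrl[i]]
    am <- amp[, idx_ctrl[i]]
    H <- 0.001 + colSums(am / (1 + ((outer(fr, fbin, function(a, b) b - a)) / bw)^2))
    seg <- pad[s:(s + win_len - 1)] * w
    spec <- fft(seg) * H
    out[s:(s + win_len - 1)] <- out[s:(s + win_len - 1)] +
      Re(fft(spec, inverse = TRUE)) / win_len * w
  }
  # Hann^2 at 50% overlap sums to a constant 3/4
  out <- out / 0.75
  out[(hop + 1):(hop + n)]
}

# deterministic per-sentence fundamental frequency (male-like range)
sentence_f0 <- function(sentence_id) {
  if (is.na(sentence_id)) {
    return(110)
  }
  100 + 18 * ((sentence_id * 7) %% 13) / 13
}

#' Synthesize the clear-speech version of a sentence specification
#'
#' A harmonic glottal source (sawtooth at the sentence's fundamental) is
#' spectrally shaped frame-by-frame so that energy ridges track the
#' specification's formant trajectories, then amplitude-modulated by the
#' syllable envelope. One `duration`-second iteration is synthesized and
#' concatenated `n_iterations` times (no time-stretching is needed because
#' the iteration duration is exact). The synthesis is deterministic given
#' the specification.
#'
#' @param spec A single row of a pool from [build_stimulus_pool()].
#' @param fs Output sampling rate (Hz); must be at least 16 kHz.
#' @param n_iterations Number of concatenated iterations (3 for the test
#'   stimuli).
#' @return An [audio_stimulus()] with `variant = "clear"`.
#' @export
synthesize_clear <- function(spec, fs = 22050, n_iterations = 3) {
  if (fs < 16000) abort("`fs` must be >= 16000 Hz")
  freq <- spec$formant_freq[[1]]
  amp <- spec$formant_amp[[1]]
  env <- spec$syllable_env[[1]]
  ctrl_fs <- spec$ctrl_fs
  if (max(freq) >= fs / 2) {
    abort("formant frequency exceeds the Nyquist frequency")
  }
  n <- round(spec$duration * fs)
  f0 <- sentence_f0(spec$sentence_id)
  t <- (seq_len(n) - 1) / fs
  f0_t <- f0 * (1 + 0.04 * sin(2 * pi * 0.7 * t))
  phase <- cumsum(f0_t) / fs
  source <- 2 * (phase %% 1) - 1
  y <- formant_shape(source, fs, freq, amp, ctrl_fs)
  env_t <- approx(seq_along(env) / ctrl_fs, env,
    xout = t + 1 / ctrl_fs, rule = 2
  )$y
  y <- y * env_t
  if (max(abs(y)) > 0) y <- y * (0.1 / rms(y))
  audio_stimulus(rep(y, n_iterations), fs, "clear",
    sentence_id = spec$sentence_id, n_iterations = n_iterations
  )
}

#' Synthesize sine-wave speech from a sentence specification
#'
#' Each formant is replaced by a single sinusoid whose instantaneous
#' frequency and amplitude follow the specification's formant tracks (no
#' formant tracking is needed: the tracks are known). The sinusoid
#' amplitudes carry only a heavily smoothed (< 1.5 Hz) remnant of the
#' syllable envelope on top of the slow formant-amplitude trajectories,
#' emulating the destruction of fine temporal (syllable-rate) structure
#' while the spectral trajectories survive.
#'
#' @inheritParams synthesize_clear
#' @return An [audio_stimulus()] with `variant = "SWS"`.
#' @export
sine_wave_synthesize <- function(spec, fs = 22050, n_iterations = 3) {
  freq <- spec$formant_freq[[1]]
  if (nrow(freq) < 2) abort("spec must define at least 2 formant tracks")
  if (max(freq) >= fs / 2) {
    abort("formant frequency exceeds the Nyquist frequency")
  }
  amp <- spec$formant_amp[[1]]
  env <- spec$syllable_env[[1]]
  ctrl_fs <- spec$ctrl_fs
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  tc <- seq_along(env) / ctrl_fs
  # syllable-rate (2-8 Hz) modulation is destroyed: keep only the slow
  # (< 1.5 Hz) trend of the envelope
  env_slow <- apply_fir(env, fir_design(ctrl_fs, high = 1.5, n_taps = 201),
    passes = 1
  )
  env_t <- approx(tc, env_slow, xout = t + 1 / ctrl_fs, rule = 2)$y
  mod <- pmax(env_t, 0) + 0.35
  y <- numeric(n)
  for (k in seq_len(nrow(freq))) {
    f_t <- approx(tc, freq[k, ], xout = t + 1 / ctrl_fs, rule = 2)$y
    a_t <- approx(tc, amp[k, ], xout = t + 1 / ctrl_fs, rule = 2)$y
    y <- y + a_t * mod * sin(2 * pi * cumsum(f_t) / fs)
  }
  if (max(abs(y)) > 0) y <- y * (0.1 / rms(y))
  audio_stimulus(rep(y, n_iterations), fs, "SWS",
    sentence_id = spec$sentence_id, n_iterations = n_iterations
  )
}

#' Noise-vocode a clear-speech stimulus
#'
#' The classic channel vocoder: the input is split into `n_bands`
#' logarithmically spaced frequency bands (100-8000 Hz), the envelope of
#' each band (half-wave rectification followed by a 30 Hz low-pass) is used
#' to modulate band-limited white noise in the same band, and the modulated
#' bands are summed. Temporal-envelope cues are preserved while spectral
#' fine structure is destroyed. The noise carrier is seeded from the
#' sentence identity so vocoding is reproducible.
#'
#' @param clear An [audio_stimulus()] with `variant = "clear"`.
#' @param n_bands Number of vocoder bands (7 for the test stimuli).
#' @param band_range Two-element numeric, outer band edges in Hz.
#' @return An [audio_stimulus()] with `variant = "NVS"`, same length and
#'   RMS as the input.
#' @export
noise_vocode <- function(clear, n_bands = 7, band_range = c(100, 8000)) {
  if (!inherits(clear, "audio_stimulus") || clear$variant != "clear") {
    abort("`clear` must be an audio_stimulus with variant \"clear\"")
  }
  if (n_bands < 2) abort("`n_bands` must be >= 2")
  x <- clear$samples
  fs <- clear$fs
  n <- length(x)
  in_rms <- rms(x)
  if (in_rms == 0) {
    return(audio_stimulus(numeric(n), fs, "NVS",
      sentence_id = clear$sentence_id, n_iterations = clear$n_iterations
    ))
  }
  edges <- exp(seq(log(band_range[1]), log(band_range[2]),
    length.out = n_bands + 1
  ))
  carrier_seed <- sub_seed(
    if (is.na(clear$sentence_id)) 0L else clear$sentence_id, "vocoder"
  )
  y <- with_seed(carrier_seed, {
    acc <- numeric(n)
    for (b in seq_len(n_bands)) {
      band <- butter_filtfilt(x, fs,
        order = 3,
        cutoff = c(edges[b], edges[b + 1]), type = "pass"
      )
      env <- butter_filtfilt(pmax(band, 0), fs,
        order = 2,
        cutoff = 30, type = "low"
      )
      env <- pmax(env, 0)
      carrier <- butter_filtfilt(rnorm(n), fs,
        order = 3,
        cutoff = c(edges[b], edges[b + 1]), type = "pass"
      )
      acc <- acc + env * carrier
    }
    acc
  })
  if (rms(y) > 0) y <- y * (in_rms / rms(y))
  audio_stimulus(y, fs, "NVS",
    sentence_id = clear$sentence_id, n_iterations = clear$n_iterations
  )
}

#' Equalize RMS amplitude across stimuli
#'
#' Scales every stimulus to a common root-mean-square amplitude, as done for
#' the degraded stimuli before presentation.
#'
#' @param stimuli A list of [audio_stimulus()] objects.
#' @param target_rms The common RMS target.
#' @return The list with samples rescaled.
#' @export
equalize_amplitude <- function(stimuli, target_rms = 0.1) {
  purrr::map(stimuli, function(s) {
    r <- rms(s$samples)
    if (r == 0) {
      abort("cannot equalize a silent stimulus: gain is undefined")
    }
    s$samples <- s$samples * (target_rms / r)
    s
  })
}
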