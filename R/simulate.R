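# Forward simulation of the study: known condition effects are injected
# into EEG envelope tracking, band-limited oscillatory power, pupil
# dilation and clarity ratings, so every downstream analysis has a
# recoverable ground truth.

PRIORS <- c("P+", "P-", "P0")

#' Specify injectable condition effects
#'
#' Gains are multiplicative on the corresponding simulated component and
#' apply to the second presentation (the presentation that follows the
#' written prior); the first presentation always uses gain 1. The rating
#' shift moves the latent clarity scale for second-presentation ratings.
#' The neutral configuration (all gains 1, shifts 0) makes the three prior
#' conditions statistically exchangeable.
#'
#' @param tracking_gain,theta_gain,alpha_gain,pupil_gain Named numeric
#'   vectors over priors (`"P+"`, `"P-"`, `"P0"`); omitted priors default
#'   to 1. All gains must be positive.
#' @param rating_shift Named numeric over priors; omitted priors default
#'   to 0.
#' @return An object of class `condition_effects`.
#' @export
#' @examples
#' condition_effects() # neutral
#' paper_like_effects() # the packaged effect configuration
condition_effects <- function(tracking_gain = NULL, theta_gain = NULL,
                              alpha_gain = NULL, pupil_gain = NULL,
                              rating_shift = NULL) {
  fill <- function(x, default) {
    out <- setNames(rep(default, 3), PRIORS)
    if (!is.null(x)) {
      bad <- setdiff(names(x), PRIORS)
      if (length(bad)) abort(paste0("unknown prior level(s): ", paste(bad, collapse = ", ")))
      out[names(x)] <- x
    }
    out
  }
  eff <- structure(
    list(
      tracking_gain = fill(tracking_gain, 1),
      theta_gain = fill(theta_gain, 1),
      alpha_gain = fill(alpha_gain, 1),
      pupil_gain = fill(pupil_gain, 1),
      rating_shift = fill(rating_shift, 0)
    ),
    class = "condition_effects"
  )
  gains <- unlist(eff[c("tracking_gain", "theta_gain", "alpha_gain", "pupil_gain")])
  if (any(gains <= 0)) abort("all gains must be > 0")
  eff
}

#' @rdname condition_effects
#' @export
paper_like_effects <- function() {
  condition_effects(
    tracking_gain = c("P+" = 1.5),
    theta_gain = c("P+" = 0.75),
    alpha_gain = c("P+" = 1.3, "P-" = 1.3),
    pupil_gain = c("P+" = 1.5, "P-" = 1.5),
    rating_shift = c("P+" = 2)
  )
}

effect_gain <- function(effects, field, prior, presentation) {
  if (presentation == 1) {
    return(if (field == "rating_shift") 0 else 1)
  }
  effects[[field]][[prior]]
}

#' Ground-truth forward temporal response function
#'
#' A rank-one channel x lag kernel: a smooth positive-then-negative
#' temporal profile over lags 0-300 ms combined with a fronto-central
#' spatial topography. Kernel energy is normalized to 1. This is the
#' minimal forward model sufficient for backward-decoder recovery, not a
#' biophysical claim.
#'
#' @param layout Sensor layout from [channel_layout()].
#' @param lags_ms Kernel lags in milliseconds.
#' @return An object of class `forward_trf`: `kernel` (channel x lag),
#'   `lags_ms`, `channels`.
#' @export
forward_trf <- function(layout, lags_ms = seq(0, 300, by = 10)) {
  tau <- lags_ms / 1000
  temporal <- dgamma_shape(tau, peak = 0.08, width = 0.035) -
    0.7 * dgamma_shape(tau, peak = 0.18, width = 0.055)
  # fronto-central peak (just anterior of the vertex)
  center <- c(0, 0.085 * sin(pi / 10), 0.085 * cos(pi / 10))
  pos <- as.matrix(layout[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(pos, 2, center)^2))
  topo <- exp(-0.5 * (d / 0.05)^2)
  kernel <- topo %o% temporal
  kernel <- kernel / sqrt(sum(kernel^2))
  structure(
    list(kernel = kernel, lags_ms = lags_ms, channels = layout$channel),
    class = "forward_trf"
  )
}

dgamma_shape <- function(t, peak, width) {
  g <- exp(-0.5 * ((t - peak) / width)^2)
  g
}

#' Default noise and component amplitudes for the EEG simulator
#'
#' Component scales (arbitrary EEG units): `tracking` scales the
#' envelope-tracking component, `theta`/`alpha` the band-limited
#' oscillations, `background` the spatially independent 1/f noise,
#' `source` the 1/f noise that shares the tracking component's topography
#' (ongoing activity in the same generators -- this is what bounds
#' decodable SNR), `onset` the stimulus-onset evoked transient.
#' `noise_scale` multiplies all stochastic components at once (used for
#' graded-degradation experiments).
#'
#' @param tracking,theta,alpha,background,source,onset,noise_scale
#'   Numeric scales.
#' @return A named list.
#' @export
default_noise_params <- function(tracking = 0.25, theta = 1.5, alpha = 1.5,
                                 background = 1, source = 1.5, onset = 0.5,
                                 noise_scale = 1) {
  list(
    tracking = tracking, theta = theta, alpha = alpha,
    background = background, source = source, onset = onset,
    noise_scale = noise_scale
  )
}

# envelope-tracking EEG component at the EEG rate: kernel convolution of
# the 100 Hz envelope, upsampled, placed at [0, dur] within the window
tracking_component <- function(envelope, trf, fs, window) {
  env <- envelope$samples
  env_fs <- envelope$fs
  n_env <- length(env)
  lag_samp <- round(trf$lags_ms / 1000 * env_fs)
  L <- matrix(0, n_env, length(lag_samp))
  for (l in seq_along(lag_samp)) {
    s <- lag_samp[l]
    if (s < n_env) L[(s + 1):n_env, l] <- env[1:(n_env - s)]
  }
  comp100 <- L %*% t(trf$kernel) # time x channel
  n_out <- round(diff(window) * fs)
  t_out <- window[1] + (seq_len(n_out) - 1) / fs
  t_env <- (seq_len(n_env) - 1) / env_fs
  out <- matrix(0, n_out, ncol(comp100))
  inside <- t_out >= 0 & t_out <= t_env[n_env]
  for (ch in seq_len(ncol(comp100))) {
    out[inside, ch] <- approx(t_env, comp100[, ch], xout = t_out[inside])$y
  }
  # unit mean channel RMS during the stimulus so gains are interpretable
  sc <- sqrt(mean(out[inside, ]^2))
  if (sc > 0) out <- out / sc
  t(out) # channel x time
}

# deterministic onset-evoked transient, identical across trials
onset_transient <- function(fs, window, layout) {
  n <- round(diff(window) * fs)
  t <- window[1] + (seq_len(n) - 1) / fs
  w <- ifelse(t >= 0 & t <= 0.7,
    exp(-t / 0.15) * sin(2 * pi * 7 * t), 0
  )
  center <- c(0, 0.085 * sin(pi / 10), 0.085 * cos(pi / 10))
  pos <- as.matrix(layout[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(pos, 2, center)^2))
  topo <- exp(-0.5 * (d / 0.06)^2)
  topo %o% w
}

#' Simulate one trial's EEG epoch
#'
#' The forward model: envelope-tracking component (kernel convolution of
#' the 2-8 Hz auditory envelope, scaled by the prior x presentation
#' tracking gain), theta-band (4-9 Hz) and alpha-band (10-15 Hz)
#' filtered-noise oscillations with fixed topographies whose amplitude is
#' modulated by the corresponding gain during the stimulus, 1/f background
#' noise, and a brief onset-evoked transient identical across trials.
#'
#' @param envelope An `auditory_envelope` (100 Hz) for the presented
#'   stimulus.
#' @param trf A [forward_trf()] kernel.
#' @param effects A [condition_effects()] object.
#' @param trial One trial record (a one-row tibble or list with `prior`,
#'   `stimulus_type`, `trial_index`).
#' @param presentation 1 or 2.
#' @param layout Sensor layout.
#' @param noise_params See [default_noise_params()].
#' @param seed Integer seed (one trial's substream).
#' @param fs EEG sampling rate (Hz).
#' @param window Epoch window in seconds around stimulus onset.
#' @return An [eeg_epoch()] (channel x sample, `t0 = window[1]`).
#' @export
simulate_trial_eeg <- function(envelope, trf, effects, trial, presentation,
                               layout, noise_params = default_noise_params(),
                               seed = 1, fs = 500, window = c(-5, 15)) {
  dur <- length(envelope$samples) / envelope$fs
  if (dur > window[2]) {
    abort(sprintf(
      "stimulus duration %.2f s exceeds the epoch window end %.2f s",
      dur, window[2]
    ))
  }
  n_ch <- nrow(layout)
  n <- round(diff(window) * fs)
  t <- window[1] + (seq_len(n) - 1) / fs
  g_track <- effect_gain(effects, "tracking_gain", trial$prior, presentation)
  g_theta <- effect_gain(effects, "theta_gain", trial$prior, presentation)
  g_alpha <- effect_gain(effects, "alpha_gain", trial$prior, presentation)
  np <- utils::modifyList(default_noise_params(), noise_params)
  ns <- np$noise_scale

  data <- np$tracking * g_track * tracking_component(envelope, trf, fs, window)

  # smooth stimulus-window gain modulation for the oscillatory components
  ramp <- stats::plogis((t - 0) / 0.2) * stats::plogis((dur - t) / 0.2)
  pos <- as.matrix(layout[, c("x", "y", "z")])
  topo_gauss <- function(center, width) {
    d <- sqrt(rowSums(sweep(pos, 2, center)^2))
    exp(-0.5 * (d / width)^2)
  }
  topo_theta <- topo_gauss(c(0, 0.05, 0.068), 0.05) # frontal-midline
  topo_alpha <- topo_gauss(c(0, -0.055, 0.065), 0.05) # parieto-occipital

  with_seed(seed, {
    if (np$theta > 0) {
      src <- band_noise(n, 1, fs, 4, 9)
      mod <- 1 + (g_theta - 1) * ramp
      data <- data + np$theta * ns * topo_theta %o% as.numeric(src * mod)
    }
    if (np$alpha > 0) {
      src <- band_noise(n, 1, fs, 10, 15)
      mod <- 1 + (g_alpha - 1) * ramp
      data <- data + np$alpha * ns * topo_alpha %o% as.numeric(src * mod)
    }
    if (np$background > 0) {
      data <- data + np$background * ns * t(pink_noise(n, n_ch))
    }
    if (np$source > 0) {
      topo_src <- sqrt(rowSums(trf$kernel^2))
      topo_src <- topo_src / sqrt(mean(topo_src^2))
      data <- data + np$source * ns * topo_src %o% drop(pink_noise(n, 1))
    }
  })
  if (np$onset > 0) {
    data <- data + np$onset * onset_transient(fs, window, layout)
  }
  rownames(data) <- layout$channel
  eeg_epoch(data, fs,
    t0 = window[1], channels = layout$channel,
    meta = list(
      trial_index = trial$trial_index, prior = trial$prior,
      stimulus_type = trial$stimulus_type, presentation = presentation
    )
  )
}

#' Build the continuous training ("audiobook") stimulus
#'
#' A single long synthetic narrative: a concatenation of clear-speech
#' segments generated from fresh sentence-like specifications. Shared
#' across participants, as one narrative was in the study design.
#'
#' @param duration Total duration in seconds.
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz).
#' @return An [audio_stimulus()] with `variant = "training"`.
#' @export
training_stimulus <- function(duration = 60, seed = 1, fs = 22050) {
  seg_dur <- 3.5
  n_seg <- ceiling(duration / seg_dur)
  pool <- build_stimulus_pool(
    n_pairs = 5 * ceiling(n_seg / 10), # pairs come in fives
    seed = sub_seed(seed, "training_pool")
  )
  segs <- lapply(seq_len(n_seg), function(i) {
    synthesize_clear(pool[i, ], fs = fs, n_iterations = 1)$samples
  })
  x <- do.call(c, segs)[seq_len(round(duration * fs))]
  audio_stimulus(x, fs, "training")
}

#' Simulate the continuous training EEG
#'
#' Forward EEG for the training narrative: tracking gain 1, no condition
#' effects, stationary oscillations and 1/f noise.
#'
#' @param envelope `auditory_envelope` of the training stimulus.
#' @param trf,layout,noise_params,seed,fs As in [simulate_trial_eeg()].
#' @return An [eeg_epoch()] spanning the narrative (`t0 = 0`).
#' @export
simulate_training_eeg <- function(envelope, trf, layout,
                                  noise_params = default_noise_params(),
                                  seed = 1, fs = 500) {
  dur <- length(envelope$samples) / envelope$fs
  trial <- list(prior = "P0", stimulus_type = "clear", trial_index = 0L)
  simulate_trial_eeg(envelope, trf, condition_effects(), trial,
    presentation = 1, layout, noise_params, seed, fs,
    window = c(0, dur)
  )
}

#' Simulate a two-eye pupil trace for one trial
#'
#' Baseline plus slow drift plus a gamma-shaped dilation response at each
#' presentation onset (scaled by the prior's pupil gain on presentation
#' 2) plus measurement noise; blinks are inserted as missing-data gaps of
#' 0.1-0.4 s on each eye independently.
#'
#' @param trial One trial record (needs `prior`, `trial_index`).
#' @param effects A [condition_effects()] object.
#' @param seed Integer seed.
#' @param fs Sampling rate (300 Hz).
#' @param onsets Presentation onsets in seconds (trial clock).
#' @param span Trace span in seconds.
#' @param blink_rate Blinks per second (0 disables blinks).
#' @param response_amp Dilation amplitude in arbitrary units.
#' @return An object of class `pupil_trace`: `left`, `right`, `fs`, `t0`,
#'   `onsets`, `meta`.
#' @export
simulate_pupil <- function(trial, effects, seed = 1, fs = 300,
                           onsets = c(0, 16), span = c(-2, 28),
                           blink_rate = 0.08, response_amp = 120) {
  n <- round(diff(span) * fs)
  t <- span[1] + (seq_len(n) - 1) / fs
  g2 <- effect_gain(effects, "pupil_gain", trial$prior, 2)
  dilation <- function(onset, amp) {
    tt <- t - onset
    resp <- ifelse(tt > 0, (tt / 1.2)^2 * exp(-tt / 1.2), 0)
    amp * resp / max(resp)
  }
  with_seed(seed, {
    base <- 1500 + rnorm(1, 0, 60)
    drift <- 30 * sin(2 * pi * runif(1, 0.01, 0.03) * t + runif(1, 0, 2 * pi))
    common <- base + drift +
      dilation(onsets[1], response_amp) +
      dilation(onsets[2], response_amp * g2)
    eyes <- lapply(1:2, function(e) {
      x <- common + rnorm(n, 0, 6)
      if (blink_rate > 0) {
        n_blinks <- stats::rpois(1, blink_rate * diff(span))
        if (n_blinks > 0) {
          starts <- runif(n_blinks, span[1], span[2] - 0.5)
          durs <- runif(n_blinks, 0.1, 0.4)
          for (b in seq_len(n_blinks)) {
            i1 <- max(1L, round((starts[b] - span[1]) * fs) + 1L)
            i2 <- min(n, i1 + round(durs[b] * fs))
            x[i1:i2] <- NA_real_
          }
        }
      }
      x
    })
    structure(
      list(
        left = eyes[[1]], right = eyes[[2]], fs = fs, t0 = span[1],
        onsets = onsets,
        meta = list(trial_index = trial$trial_index, prior = trial$prior)
      ),
      class = "pupil_trace"
    )
  })
}

#' Fill in ordinal clarity ratings for a design
#'
#' Latent-threshold model: a latent Gaussian equal to a stimulus-type
#' base level plus the prior's rating shift (second presentation only)
#' plus unit-variance noise, cut at three fixed thresholds into the
#' ordinal 1-4 clarity scale (1 = understood nothing, 4 = understood
#' everything).
#'
#' @param design Trial records from [assign_conditions()].
#' @param effects A [condition_effects()] object.
#' @param seed Integer seed.
#' @param base Named base levels of the latent scale per stimulus type.
#' @param thresholds Three increasing cut points.
#' @return The design with `clarity_1`, `clarity_2` filled (integers 1-4).
#' @export
simulate_ratings <- function(design, effects, seed = 1,
                             base = c(SWS = 0.3, NVS = 0),
                             thresholds = c(-0.6, 0.8, 2)) {
  n <- nrow(design)
  with_seed(sub_seed(seed, "ratings"), {
    b <- base[design$stimulus_type]
    shift <- vapply(
      design$prior, function(p) effects$rating_shift[[p]],
      numeric(1)
    )
    lat1 <- b + rnorm(n)
    lat2 <- b + shift + rnorm(n)
    design$clarity_1 <- as.integer(findInterval(lat1, thresholds) + 1L)
    design$clarity_2 <- as.integer(findInterval(lat2, thresholds) + 1L)
  })
  design
}

#' Precompute auditory envelopes for the sentences of a design
#'
#' Synthesizes each presented sentence in its assigned variant and runs it
#' through the auditory model once; results are keyed
#' `"<sentence_id>_<variant>"`. An existing bank can be passed in and is
#' extended only with missing entries, so envelope work is shared across
#' participants and replicate datasets.
#'
#' @param pool Stimulus pool.
#' @param design Trial records (uses `sentence_id`, `stimulus_type`).
#' @param n_iterations Iterations per presentation.
#' @param fs Audio sampling rate.
#' @param bank Optional existing bank (an environment) to extend.
#' @return An environment mapping keys to `auditory_envelope` objects.
#' @export
build_envelope_bank <- function(pool, design, n_iterations = 3, fs = 22050,
                                bank = NULL) {
  if (is.null(bank)) bank <- new.env(parent = emptyenv())
  need <- unique(design[, c("sentence_id", "stimulus_type")])
  for (i in seq_len(nrow(need))) {
    sid <- need$sentence_id[i]
    var <- need$stimulus_type[i]
    key <- paste0(sid, "_", var)
    if (!is.null(bank[[key]])) next
    spec <- pool[pool$sentence_id == sid, ]
    audio <- if (var == "SWS") {
      sine_wave_synthesize(spec, fs = fs, n_iterations = n_iterations)
    } else {
      noise_vocode(
        synthesize_clear(spec, fs = fs, n_iterations = n_iterations)
      )
    }
    bank[[key]] <- extract_envelope(audio)
  }
  bank
}

#' Simulate a full experimental session for one participant
#'
#' Generates the design, clarity ratings, the shared training narrative
#' with its EEG, all requested trial EEG epochs (both presentations) and
#' pupil traces. Fully deterministic given `(pool, participant_index,
#' effects, seed)` and the configuration.
#'
#' @param pool Stimulus pool from [build_stimulus_pool()].
#' @param participant_index Positive integer.
#' @param effects A [condition_effects()] object.
#' @param seed Integer master seed.
#' @param layout Sensor layout.
#' @param trials_per_cell Optional cap on trials per stimulus-type x prior
#'   cell (desk-scale runs).
#' @param presentations Presentations to simulate (default both).
#' @param epoch_window EEG epoch window (s around onset).
#' @param n_iterations Sentence iterations per presentation.
#' @param training_duration Training narrative duration (s).
#' @param noise_params See [default_noise_params()].
#' @param fs_eeg EEG sampling rate.
#' @param envelope_bank Optional precomputed envelope bank.
#' @param simulate_pupil_traces Logical; include pupil simulation.
#' @return An object of class `popout_session` with elements `design`,
#'   `training` (`audio`, `envelope`, `eeg`), `trials` (named
#'   `trial<k>_pres<p>`), `pupil`, `effects`, `meta` (seed provenance).
#' @export
simulate_session <- function(pool, participant_index, effects, seed,
                             layout = channel_layout(),
                             trials_per_cell = NULL,
                             presentations = c(1, 2),
                             epoch_window = c(-5, 15),
                             n_iterations = 3,
                             training_duration = 60,
                             noise_params = default_noise_params(),
                             fs_eeg = 500,
                             envelope_bank = NULL,
                             simulate_pupil_traces = TRUE) {
  design <- assign_conditions(pool, participant_index, seed)
  if (!is.null(trials_per_cell)) {
    design <- design |>
      dplyr::group_by(.data$stimulus_type, .data$prior) |>
      dplyr::slice_head(n = trials_per_cell) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$trial_index)
  }
  design <- simulate_ratings(design, effects, sub_seed(seed, "ratings", participant_index))

  trf <- forward_trf(layout)
  train_audio <- training_stimulus(training_duration, seed)
  train_env <- extract_envelope(train_audio)
  train_eeg <- simulate_training_eeg(
    train_env, trf, layout, noise_params,
    seed = sub_seed(seed, "training_eeg", participant_index), fs = fs_eeg
  )

  bank <- build_envelope_bank(pool, design,
    n_iterations = n_iterations,
    bank = envelope_bank
  )
  trials <- list()
  pupil <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    env <- bank[[paste0(tr$sentence_id, "_", tr$stimulus_type)]]
    for (p in presentations) {
      trials[[sprintf("trial%03d_pres%d", tr$trial_index, p)]] <-
        simulate_trial_eeg(
          env, trf, effects, tr, p, layout, noise_params,
          seed = sub_seed(seed, "trial_eeg", participant_index, tr$trial_index, p),
          fs = fs_eeg, window = epoch_window
        )
    }
    if (simulate_pupil_traces) {
      pupil[[sprintf("trial%03d", tr$trial_index)]] <- simulate_pupil(
        tr, effects,
        seed = sub_seed(seed, "pupil", participant_index, tr$trial_index)
      )
    }
  }
  structure(
    list(
      design = design,
      training = list(audio = train_audio, envelope = train_env, eeg = train_eeg),
      trials = trials,
      pupil = pupil,
      effects = effects,
      meta = list(
        participant_index = participant_index, seed = seed,
        fs_eeg = fs_eeg, epoch_window = epoch_window,
        n_iterations = n_iterations,
        training_duration = training_duration
      )
    ),
    class = "popout_session"
  )
}

#' @export
print.popout_session <- function(x, ...) {
  cat(sprintf(
    "<popout_session> participant %d: %d trials, %d EEG epochs, %d pupil traces\n",
    x$meta$participant_index, nrow(x$design), length(x$trials), length(x$pupil)
  ))
  invisible(x)
}
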