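# Shared fixtures, memoized so expensive objects (stimulus pools, auditory
# envelopes, trained decoders) are built once per test run and reused by
# every file that needs them.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# a contiguous central 16-channel patch of the packaged 64-channel
# template (a connected montage for scaled-down spatial cluster tests)
patch16_layout <- function() {
  memo("patch16", function() {
    lay <- channel_layout()
    patch <- c(
      "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "FC3", "FC1", "FC2",
      "FC4", "CP3", "CP1", "CPz", "CP2", "CP4"
    )
    lay[match(patch, lay$channel), ]
  })
}

fix_layout <- function() memo("layout", channel_layout)
fix_graph <- function() memo("graph", function() build_neighbors(fix_layout()))
fix_trf <- function() memo("trf", function() forward_trf(fix_layout()))

# 10-pair pool used by the design unit tests
fix_pool10 <- function() memo("pool10", function() build_stimulus_pool(10, seed = 101))

# small pool for audio/unit tests
fix_pool5 <- function() memo("pool5", function() build_stimulus_pool(5, seed = 2))

# one NVS stimulus envelope (single iteration) for decoder-level tests
fix_env_nvs <- function() {
  memo("env_nvs", function() {
    extract_envelope(noise_vocode(
      synthesize_clear(fix_pool5()[1, ], n_iterations = 1)
    ))
  })
}

# shared pipeline resources for the acceptance-scale runs: pool of 15
# pairs, 30 s training narrative, decoders trained lazily per participant
fix_resources <- function() {
  memo("resources", function() {
    popout:::pipeline_resources(accept_config(seed = 1))
  })
}

# the acceptance-scale run configuration (seed varies across replicates,
# pool/decoders stay fixed via pool_seed)
accept_config <- function(seed, effects = condition_effects(),
                          trials_per_cell = 3,
                          priors = c("P+", "P0"),
                          measures = "reconstruction") {
  run_config(
    n_participants = 19, n_pairs = 15, seed = seed, effects = effects,
    trials_per_cell = trials_per_cell, presentations = 2,
    priors = priors, n_iterations = 1, training_duration = 30,
    epoch_window = c(-0.5, 4), lambda = 1e4, measures = measures,
    pool_seed = 101
  )
}

# per-participant mean reconstruction-score difference P+ minus P0
# (iteration 1, presentation 2), pooled over stimulus types
delta_r_by_participant <- function(bundle) {
  bundle$scores |>
    dplyr::filter(.data$iteration == 1) |>
    dplyr::group_by(.data$participant, .data$prior) |>
    dplyr::summarise(r = mean(.data$r, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "prior", values_from = "r") |>
    dplyr::mutate(delta = .data$`P+` - .data$P0)
}

# clear/NVS/SWS envelope correlations over the 10-sentence pool
# (computed once; shared by the audio property test and acceptance)
env_corr_pool <- function() {
  memo("env_corr", function() {
    pool <- fix_pool5()
    r_nvs <- r_sws <- numeric(10)
    for (i in 1:10) {
      cl <- synthesize_clear(pool[i, ], n_iterations = 1)
      e_cl <- extract_envelope(cl)
      r_nvs[i] <- cor(e_cl$samples, extract_envelope(noise_vocode(cl))$samples)
      r_sws[i] <- cor(
        e_cl$samples,
        extract_envelope(sine_wave_synthesize(pool[i, ], n_iterations = 1))$samples
      )
    }
    tibble::tibble(sentence = 1:10, r_nvs = r_nvs, r_sws = r_sws)
  })
}

# noiseless-component simulator settings
silent_noise <- function() {
  default_noise_params(
    tracking = 1, theta = 0, alpha = 0, background = 0,
    source = 0, onset = 0
  )
}

# a decoder trained on noiseless training data (for forward/backward
# consistency checks)
fix_clean_decoder <- function() {
  memo("clean_decoder", function() {
    res <- fix_resources()
    eeg <- simulate_training_eeg(res$train_env, res$trf, res$layout,
      silent_noise(),
      seed = 99
    )
    dur <- length(res$train_env$samples) / res$train_env$fs
    train_decoder(prepare_for_decoding(eeg, dur), res$train_env,
      lambda_grid = 1
    )
  })
}

# decode one simulated trial and return iteration scores
simulate_and_score <- function(model, env, prior, presentation, effects,
                               noise_params, seed,
                               window = c(-0.5, 4)) {
  res <- fix_resources()
  tr <- list(prior = prior, stimulus_type = "NVS", trial_index = 1L)
  ep <- simulate_trial_eeg(
    env, res$trf, effects, tr, presentation, res$layout,
    noise_params,
    seed = seed, window = window
  )
  dur <- length(env$samples) / env$fs
  est <- reconstruct_envelope(model, prepare_for_decoding(ep, dur))
  score_reconstruction(est, env)
}
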