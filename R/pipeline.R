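# Orchestration: simulate -> preprocess -> envelope -> decode -> spectra ->
# pupil -> condition summaries, driven by a single validated configuration.

#' Pipeline run configuration
#'
#' Collects every stage parameter with validated defaults. The defaults
#' mirror the emulated study (19 participants, 80 sentence pairs, 3
#' iterations per presentation, both presentations); desk-scale runs
#' shrink `n_pairs`, `trials_per_cell`, `n_iterations` and
#' `training_duration`.
#'
#' @param n_participants Number of participants.
#' @param n_pairs Sentence pairs in the pool (divisible by 5).
#' @param seed Master seed for the run.
#' @param effects A [condition_effects()] object.
#' @param trials_per_cell Optional per-cell trial cap.
#' @param presentations Presentations to simulate.
#' @param stimulus_types,priors Conditions to include.
#' @param n_iterations Sentence iterations per presentation.
#' @param training_duration Training narrative duration (s).
#' @param epoch_window Trial EEG window (s).
#' @param noise_params See [default_noise_params()].
#' @param fs_eeg EEG rate (Hz).
#' @param lambda Ridge penalty; a vector triggers cross-validation.
#' @param measures Character subset of `"reconstruction"`, `"bandpower"`,
#'   `"pupil"`, `"ratings"`.
#' @param tf_window Band-power analysis window (s).
#' @param pool_seed Seed for the stimulus pool and decoder training;
#'   defaults to `seed`. Keeping it fixed while varying `seed` produces
#'   replicate datasets over the same stimuli and decoders.
#' @return A validated `run_config` list.
#' @export
run_config <- function(n_participants = 19, n_pairs = 80, seed = 1,
                       effects = condition_effects(),
                       trials_per_cell = NULL,
                       presentations = c(1, 2),
                       stimulus_types = c("SWS", "NVS"),
                       priors = c("P+", "P-", "P0"),
                       n_iterations = 3,
                       training_duration = 60,
                       epoch_window = NULL,
                       noise_params = default_noise_params(),
                       fs_eeg = 500,
                       lambda = 100,
                       measures = c("reconstruction", "ratings"),
                       tf_window = c(0.5, 3),
                       pool_seed = NULL) {
  stopifnot(
    n_participants >= 1, n_pairs %% 5 == 0,
    all(presentations %in% 1:2),
    all(stimulus_types %in% c("SWS", "NVS")),
    all(priors %in% PRIORS),
    all(measures %in% c("reconstruction", "bandpower", "pupil", "ratings"))
  )
  stim_dur <- 3.5 * n_iterations
  if (is.null(epoch_window)) {
    epoch_window <- c(-1, stim_dur + 1)
  }
  if (epoch_window[2] < stim_dur) {
    abort("epoch window must cover the stimulus duration")
  }
  structure(
    list(
      n_participants = n_participants, n_pairs = n_pairs, seed = seed,
      effects = effects, trials_per_cell = trials_per_cell,
      presentations = presentations, stimulus_types = stimulus_types,
      priors = priors, n_iterations = n_iterations,
      training_duration = training_duration, epoch_window = epoch_window,
      noise_params = noise_params, fs_eeg = fs_eeg, lambda = lambda,
      measures = measures, tf_window = tf_window,
      pool_seed = pool_seed %||% seed, stim_dur = stim_dur
    ),
    class = "run_config"
  )
}

# shared-resource store for replicate runs: pool, layout, forward kernel,
# training envelope, envelope bank, trained decoders
pipeline_resources <- function(config, reuse = NULL) {
  if (!is.null(reuse)) {
    return(reuse)
  }
  res <- new.env(parent = emptyenv())
  res$layout <- channel_layout()
  res$graph <- build_neighbors(res$layout)
  res$trf <- forward_trf(res$layout)
  res$pool <- build_stimulus_pool(config$n_pairs, config$pool_seed)
  res$train_env <- extract_envelope(
    training_stimulus(config$training_duration, config$pool_seed)
  )
  res$bank <- new.env(parent = emptyenv())
  res$decoders <- list()
  res
}

pipeline_decoder <- function(res, config, participant) {
  key <- as.character(participant)
  if (!is.null(res$decoders[[key]])) {
    return(res$decoders[[key]])
  }
  train_eeg <- simulate_training_eeg(
    res$train_env, res$trf, res$layout, config$noise_params,
    seed = sub_seed(config$pool_seed, "training_eeg", participant),
    fs = config$fs_eeg
  )
  dur <- length(res$train_env$samples) / res$train_env$fs
  ready <- prepare_for_decoding(train_eeg, dur)
  model <- train_decoder(ready, res$train_env, lambda_grid = config$lambda)
  res$decoders[[key]] <- model
  model
}

#' Run the full analysis pipeline
#'
#' Executes, per participant: design generation, clarity ratings, decoder
#' training on the shared clear-speech narrative, trial EEG simulation and
#' preprocessing, envelope reconstruction and scoring, band-power
#' extraction, and pupil preprocessing. Trial EEG is simulated, processed
#' and discarded one epoch at a time, so memory stays flat.
#'
#' @param config A [run_config()].
#' @param reuse Optional resource store returned in a previous bundle's
#'   `resources` element; shares the pool, envelope bank and trained
#'   decoders across replicate runs.
#' @return A `popout_results` bundle: tibbles `scores`, `bandpower`,
#'   `design` (with ratings), `pupil_cells` / `spectra_cells` (per-cell
#'   participant arrays for cluster statistics), the `config`, and
#'   `resources` for reuse.
#' @export
run_pipeline <- function(config, reuse = NULL) {
  res <- pipeline_resources(config, reuse)
  scores <- list()
  bandpower <- list()
  designs <- list()
  spectra <- list() # cell -> list of participant channel x freq matrices
  pupil_cells <- list() # cell -> list of participant time vectors
  bands <- power_bands()

  for (pp in seq_len(config$n_participants)) {
    design <- assign_conditions(res$pool, pp, config$seed)
    design <- design[
      design$stimulus_type %in% config$stimulus_types &
        design$prior %in% config$priors, ,
      drop = FALSE
    ]
    if (!is.null(config$trials_per_cell)) {
      design <- design |>
        dplyr::group_by(.data$stimulus_type, .data$prior) |>
        dplyr::slice_head(n = config$trials_per_cell) |>
        dplyr::ungroup()
    }
    if ("ratings" %in% config$measures) {
      design <- simulate_ratings(
        design, config$effects,
        sub_seed(config$seed, "ratings", pp)
      )
    }
    designs[[pp]] <- dplyr::mutate(design, participant = pp, .before = 1)

    decoder <- if ("reconstruction" %in% config$measures) {
      pipeline_decoder(res, config, pp)
    }
    build_envelope_bank(res$pool, design,
      n_iterations = config$n_iterations, bank = res$bank
    )

    pp_spectra <- list()
    pp_pupil <- list()
    for (i in seq_len(nrow(design))) {
      tr <- design[i, ]
      env <- res$bank[[paste0(tr$sentence_id, "_", tr$stimulus_type)]]
      for (pres in config$presentations) {
        need_eeg <- any(c("reconstruction", "bandpower") %in% config$measures)
        if (need_eeg) {
          epoch <- simulate_trial_eeg(
            env, res$trf, config$effects, tr, pres, res$layout,
            config$noise_params,
            seed = sub_seed(config$seed, "trial_eeg", pp, tr$trial_index, pres),
            fs = config$fs_eeg, window = config$epoch_window
          )
        }
        if ("reconstruction" %in% config$measures) {
          ready <- prepare_for_decoding(epoch, config$stim_dur)
          est <- reconstruct_envelope(decoder, ready)
          sc <- score_reconstruction(est, env)
          scores[[length(scores) + 1]] <- dplyr::mutate(sc,
            participant = pp, trial_index = tr$trial_index,
            stimulus_type = tr$stimulus_type, prior = tr$prior,
            presentation = pres, .before = 1
          )
        }
        if ("bandpower" %in% config$measures) {
          masto <- rereference(epoch, "linked_mastoids")
          tfr <- tf_decompose(masto, time_range = config$tf_window + c(-0.5, 0.5))
          f_t <- which(tfr$times >= config$tf_window[1] - 1e-9 &
            tfr$times <= config$tf_window[2] + 1e-9)
          pw <- apply(tfr$power[, , f_t, drop = FALSE], c(1, 2), mean)
          cell <- paste(tr$stimulus_type, tr$prior, pres, sep = "_")
          if (is.null(pp_spectra[[cell]])) pp_spectra[[cell]] <- list()
          pp_spectra[[cell]][[length(pp_spectra[[cell]]) + 1]] <- pw
          for (b in names(bands)) {
            ba <- band_average(tfr, b, window = config$tf_window)
            bandpower[[length(bandpower) + 1]] <- dplyr::mutate(ba,
              participant = pp, trial_index = tr$trial_index,
              stimulus_type = tr$stimulus_type, prior = tr$prior,
              presentation = pres, .before = 1
            )
          }
        }
      }
      if ("pupil" %in% config$measures) {
        trace <- simulate_pupil(
          tr, config$effects,
          seed = sub_seed(config$seed, "pupil", pp, tr$trial_index)
        )
        prep <- preprocess_pupil(trace)
        if (!prep$dropout) {
          ep2 <- prep$epochs[[2]]
          dec <- round(ep2$fs / 10)
          cell <- paste(tr$stimulus_type, tr$prior, sep = "_")
          if (is.null(pp_pupil[[cell]])) pp_pupil[[cell]] <- list()
          pp_pupil[[cell]][[length(pp_pupil[[cell]]) + 1]] <-
            ep2$samples[seq(1, length(ep2$samples), by = dec)]
        }
      }
    }
    # participant-level cell aggregates for the cluster tests
    for (cell in names(pp_spectra)) {
      avg <- log10(Reduce(`+`, pp_spectra[[cell]]) / length(pp_spectra[[cell]]))
      spectra[[cell]] <- c(spectra[[cell]], list(avg))
    }
    for (cell in names(pp_pupil)) {
      avg <- Reduce(`+`, pp_pupil[[cell]]) / length(pp_pupil[[cell]])
      pupil_cells[[cell]] <- c(pupil_cells[[cell]], list(avg))
    }
  }

  as_array3 <- function(lst) {
    a <- array(0, c(length(lst), dim(lst[[1]])))
    for (i in seq_along(lst)) a[i, , ] <- lst[[i]]
    a
  }
  structure(
    list(
      scores = if (length(scores)) dplyr::bind_rows(scores) else NULL,
      bandpower = if (length(bandpower)) dplyr::bind_rows(bandpower) else NULL,
      design = dplyr::bind_rows(designs),
      spectra_cells = lapply(spectra, as_array3),
      pupil_cells = lapply(pupil_cells, function(l) do.call(rbind, l)),
      config = config,
      resources = res
    ),
    class = "popout_results"
  )
}

#' @export
print.popout_results <- function(x, ...) {
  cat("<popout_results>\n")
  cat(sprintf(
    "  participants: %d, trials: %d\n",
    x$config$n_participants, nrow(x$design)
  ))
  if (!is.null(x$scores)) {
    cat(sprintf("  reconstruction scores: %d rows\n", nrow(x$scores)))
  }
  if (!is.null(x$bandpower)) {
    cat(sprintf("  band power rows: %d\n", nrow(x$bandpower)))
  }
  invisible(x)
}

#' Condition cell means and descriptive paired tests
#'
#' Summarizes every measure in a results bundle into per-participant cell
#' means (stimulus type x prior), and compares each informative prior
#' against P0 with paired Wilcoxon signed-rank tests. These tests are
#' descriptive conveniences; model-based inference is left to external
#' tools on the exported tables.
#'
#' @param bundle A [run_pipeline()] result.
#' @param iteration Reconstruction-score iteration used (1, the first
#'   3.5 s).
#' @param presentation Presentation summarized (2, after the prior).
#' @return A list with `cell_means` (tibble measure x participant x cell)
#'   and `contrasts` (tibble of paired differences vs P0 with p-values).
#' @export
summarize_conditions <- function(bundle, iteration = 1, presentation = 2) {
  cm <- list()
  if (!is.null(bundle$scores)) {
    cm$reconstruction <- bundle$scores |>
      dplyr::filter(
        .data$iteration == !!iteration,
        .data$presentation == !!presentation
      ) |>
      dplyr::group_by(.data$participant, .data$stimulus_type, .data$prior) |>
      dplyr::summarise(value = mean(.data$r, na.rm = TRUE), .groups = "drop")
  }
  if (!is.null(bundle$bandpower)) {
    cm_bp <- bundle$bandpower |>
      dplyr::filter(.data$presentation == !!presentation) |>
      dplyr::group_by(
        .data$participant, .data$stimulus_type, .data$prior,
        .data$band
      ) |>
      dplyr::summarise(value = mean(.data$log_power), .groups = "drop")
    for (b in unique(cm_bp$band)) {
      cm[[paste0("power_", b)]] <- cm_bp |>
        dplyr::filter(.data$band == b) |>
        dplyr::select(-"band")
    }
  }
  if (length(bundle$pupil_cells)) {
    rows <- list()
    for (cell in names(bundle$pupil_cells)) {
      parts <- strsplit(cell, "_")[[1]]
      m <- bundle$pupil_cells[[cell]]
      rows[[cell]] <- tibble::tibble(
        participant = seq_len(nrow(m)),
        stimulus_type = parts[1], prior = parts[2],
        value = rowMeans(m)
      )
    }
    cm$pupil <- dplyr::bind_rows(rows)
  }
  if ("clarity_2" %in% names(bundle$design) &&
    !all(is.na(bundle$design$clarity_2))) {
    cm$clarity <- bundle$design |>
      dplyr::group_by(.data$participant, .data$stimulus_type, .data$prior) |>
      dplyr::summarise(
        value = mean(.data$clarity_2, na.rm = TRUE),
        .groups = "drop"
      )
  }
  cell_means <- dplyr::bind_rows(cm, .id = "measure")

  contrasts <- cell_means |>
    tidyr::pivot_wider(names_from = "prior", values_from = "value") |>
    tidyr::pivot_longer(dplyr::any_of(c("P+", "P-")),
      names_to = "prior", values_to = "informed"
    ) |>
    dplyr::filter(!is.na(.data$informed), !is.na(.data$P0)) |>
    dplyr::group_by(.data$measure, .data$stimulus_type, .data$prior) |>
    dplyr::summarise(
      mean_diff = mean(.data$informed - .data$P0),
      p_value = tryCatch(
        wilcox.test(.data$informed, .data$P0, paired = TRUE, exact = FALSE)$p.value,
        error = function(e) NA_real_
      ),
      n = dplyr::n(),
      .groups = "drop"
    )
  list(cell_means = cell_means, contrasts = contrasts)
}
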