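#' Build a pool of paired synthetic sentence specifications
#'
#' Generates `2 * n_pairs` parametric "sentence" specifications organised as
#' pairs with similar (but not identical) structure, partitioned into 5
#' equally sized stimulus lists (A-E). Each specification carries four
#' formant frequency/amplitude trajectories (sampled at a 100 Hz control
#' rate) and a nonnegative syllable envelope with dominant energy in the
#' 2-8 Hz range. The second member of each pair is a bounded perturbation of
#' the first: formant tracks rescaled by at most +/-10% and syllable timing
#' jittered, which preserves within-pair similarity without any language
#' assets.
#'
#' @param n_pairs Number of sentence pairs; must be divisible by 5 so the
#'   five lists are complete.
#' @param seed Integer seed; the pool is reproducible bit-for-bit.
#' @param duration Duration in seconds of a single sentence iteration.
#' @return A tibble with one row per sentence: `sentence_id`, `pair_id`,
#'   `list_id`, `duration`, `ctrl_fs`, and list-columns `formant_freq`,
#'   `formant_amp` (4 x time matrices, Hz / linear amplitude) and
#'   `syllable_env` (nonnegative modulation trajectory).
#' @export
#' @examples
#' pool <- build_stimulus_pool(5, seed = 1)
#' table(pool$list_id)
build_stimulus_pool <- function(n_pairs, seed, duration = 3.5) {
  if (n_pairs < 1) abort("`n_pairs` must be >= 1")
  if (n_pairs %% 5 != 0) {
    abort(paste0(
      "`n_pairs` must be divisible by 5 so that the 5 stimulus lists ",
      "(A-E) are complete; got ", n_pairs
    ))
  }
  ctrl_fs <- 100
  n_ctrl <- round(duration * ctrl_fs)
  f_centers <- c(500, 1500, 2600, 3600)
  f_ranges <- c(150, 400, 300, 250)
  a_base <- c(1, 0.55, 0.3, 0.18)

  smooth_curve <- function(n, rate_hz = 1.5, n_comp = 4) {
    t <- (seq_len(n) - 1) / ctrl_fs
    f <- runif(n_comp, 0.3, rate_hz)
    ph <- runif(n_comp, 0, 2 * pi)
    a <- runif(n_comp, 0.3, 1)
    z <- colSums(a * sin(outer(2 * pi * f, t) + ph))
    z / max(1e-9, max(abs(z)))
  }

  syllable_envelope <- function(n, onsets = NULL) {
    t <- (seq_len(n) - 1) / ctrl_fs
    if (is.null(onsets)) {
      gaps <- rgamma(ceiling(duration * 6), shape = 8, rate = 8 / 0.25)
      onsets <- cumsum(pmax(gaps, 0.12))
      onsets <- onsets[onsets < duration - 0.1]
    }
    env <- numeric(n)
    width <- 0.09 # s.d. of each syllable bump, seconds
    amps <- runif(length(onsets), 0.6, 1)
    for (i in seq_along(onsets)) {
      env <- env + amps[i] * exp(-0.5 * ((t - onsets[i]) / width)^2)
    }
    env / max(env)
  }

  specs <- with_seed(sub_seed(seed, "pool"), {
    out <- vector("list", 2 * n_pairs)
    for (p in seq_len(n_pairs)) {
      freq <- t(vapply(seq_along(f_centers), function(k) {
        f_centers[k] + f_ranges[k] * smooth_curve(n_ctrl)
      }, numeric(n_ctrl)))
      amp <- t(vapply(seq_along(a_base), function(k) {
        a_base[k] * (0.7 + 0.3 * (smooth_curve(n_ctrl) + 1) / 2)
      }, numeric(n_ctrl)))
      env1 <- syllable_envelope(n_ctrl)
      # pair mate: bounded perturbation of member 1
      scale_k <- runif(4, 0.9, 1.1)
      freq2 <- freq * scale_k
      amp2 <- amp * runif(4, 0.85, 1.15)
      env2 <- syllable_envelope(n_ctrl)
      out[[2 * p - 1]] <- list(freq = freq, amp = amp, env = env1)
      out[[2 * p]] <- list(freq = freq2, amp = amp2, env = env2)
    }
    out
  })

  pool <- tibble::tibble(
    sentence_id = seq_len(2 * n_pairs),
    pair_id = rep(seq_len(n_pairs), each = 2),
    list_id = rep(LETTERS[1:5], each = 2 * n_pairs / 5),
    duration = duration,
    ctrl_fs = ctrl_fs,
    formant_freq = purrr::map(specs, "freq"),
    formant_amp = purrr::map(specs, "amp"),
    syllable_env = purrr::map(specs, "env")
  )
  stopifnot(all(vapply(pool$formant_freq, function(m) {
    all(m > 90 & m < 8000)
  }, logical(1))))
  pool
}

#' Assign stimuli to conditions for one participant
#'
#' Builds the within-participant design: with `k` pairs per list the design
#' has `6 * k` trials in 6 blocks (96 trials in blocks of 16 at the full
#' pool size of 80 pairs). Four lists feed the informative-prior cells
#' (SWS/NVS crossed with P+/P-), using one member of each pair; the fifth
#' list is split between the two neutral-prior (P0) cells, one pair member
#' to each. The list-to-condition mapping rotates with `participant_index`
#' as a 5 x 5 Latin square, so across participants 1..5 every list serves
#' every condition role exactly once.
#'
#' @param pool A stimulus pool from [build_stimulus_pool()].
#' @param participant_index Positive integer; determines the Latin-square
#'   rotation (modulo 5).
#' @param seed Integer seed controlling pair-member selection and trial
#'   order.
#' @return A tibble of trial records: `trial_index`, `block`,
#'   `stimulus_type` (`"SWS"`/`"NVS"`), `prior` (`"P+"`, `"P-"`, `"P0"`),
#'   `sentence_id`, `displayed_sentence_id` (`NA` for P0; the pair mate for
#'   P-), `pair_id`, `list_id`, and empty ordinal rating columns
#'   `clarity_1`, `clarity_2`.
#' @export
assign_conditions <- function(pool, participant_index, seed) {
  req <- c("sentence_id", "pair_id", "list_id")
  if (!all(req %in% names(pool))) {
    abort("`pool` is malformed: expected columns sentence_id, pair_id, list_id")
  }
  lists <- sort(unique(pool$list_id))
  if (!identical(lists, LETTERS[1:5])) {
    abort("`pool` is malformed: expected 5 complete lists A-E")
  }
  per_list <- dplyr::count(pool, .data$list_id)
  if (length(unique(per_list$n)) != 1L || any(per_list$n %% 2 != 0)) {
    abort("`pool` is malformed: lists must hold equal numbers of complete pairs")
  }
  k <- per_list$n[1] / 2 # pairs per list

  roles <- c("SWS_P+", "SWS_P-", "NVS_P+", "NVS_P-", "P0")
  rot <- (participant_index - 1L) %% 5L
  role_list <- LETTERS[((seq_along(roles) - 1L + rot) %% 5L) + 1L]
  names(role_list) <- roles

  with_seed(sub_seed(seed, "design", participant_index), {
    pick_members <- function(list_id) {
      sub <- pool[pool$list_id == list_id, req]
      pairs <- unique(sub$pair_id)
      picked <- t(vapply(pairs, function(p) {
        ids <- sub$sentence_id[sub$pair_id == p]
        i <- sample.int(2, 1)
        c(ids[i], ids[3 - i])
      }, integer(2)))
      tibble::tibble(
        pair_id = pairs,
        presented = picked[, 1], other = picked[, 2]
      )
    }
    records <- list()
    for (role in roles[1:4]) {
      parts <- strsplit(role, "_")[[1]]
      picks <- pick_members(role_list[[role]])
      records[[role]] <- tibble::tibble(
        stimulus_type = parts[1],
        prior = parts[2],
        sentence_id = picks$presented,
        displayed_sentence_id = if (parts[2] == "P+") {
          picks$presented
        } else {
          picks$other
        },
        pair_id = picks$pair_id,
        list_id = role_list[[role]]
      )
    }
    # neutral list: one member of each pair to SWS-P0, the other to NVS-P0
    split0 <- pick_members(role_list[["P0"]])
    records[["SWS_P0"]] <- tibble::tibble(
      stimulus_type = "SWS", prior = "P0",
      sentence_id = split0$presented, displayed_sentence_id = NA_integer_,
      pair_id = split0$pair_id, list_id = role_list[["P0"]]
    )
    records[["NVS_P0"]] <- tibble::tibble(
      stimulus_type = "NVS", prior = "P0",
      sentence_id = split0$other, displayed_sentence_id = NA_integer_,
      pair_id = split0$pair_id, list_id = role_list[["P0"]]
    )
    design <- dplyr::bind_rows(records)
    design <- design[sample.int(nrow(design)), ]
    design$trial_index <- seq_len(nrow(design))
    design$block <- rep(seq_len(6), each = k)
    design$clarity_1 <- NA_integer_
    design$clarity_2 <- NA_integer_
    dplyr::select(
      design, "trial_index", "block", "stimulus_type", "prior",
      "sentence_id", "displayed_sentence_id", "pair_id", "list_id",
      "clarity_1", "clarity_2"
    )
  })
}
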