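# Forward EEG/pupil simulation and full-session generation.

test_that("condition effects validate their inputs", {
  eff <- condition_effects(tracking_gain = c("P+" = 1.5))
  expect_equal(eff$tracking_gain[["P+"]], 1.5)
  expect_equal(eff$tracking_gain[["P0"]], 1)
  expect_error(condition_effects(theta_gain = c("Q" = 1)), "unknown prior")
  expect_error(condition_effects(alpha_gain = c("P+" = -1)), "> 0")
  # presentation 1 is never scaled
  expect_equal(popout:::effect_gain(paper_like_effects(), "tracking_gain", "P+", 1), 1)
  expect_equal(popout:::effect_gain(paper_like_effects(), "tracking_gain", "P+", 2), 1.5)
})

test_that("the forward kernel is normalized and fronto-central", {
  lay <- fix_layout()
  trf <- forward_trf(lay)
  expect_equal(dim(trf$kernel), c(64, 31))
  expect_equal(sum(trf$kernel^2), 1, tolerance = 1e-12)
  topo <- sqrt(rowSums(trf$kernel^2))
  frontocentral <- c("FC1", "FC2", "Cz", "C1", "C2")
  posterior <- c("O1", "O2", "PO7", "PO8")
  expect_gt(
    mean(topo[match(frontocentral, lay$channel)]),
    3 * mean(topo[match(posterior, lay$channel)])
  )
})

test_that("trial epochs have the acquisition geometry", {
  lay <- fix_layout()
  trf <- fix_trf()
  env <- fix_env_nvs()
  tr <- list(prior = "P0", stimulus_type = "NVS", trial_index = 1L)
  # full-scale window: 64 channels x 500 Hz x 20 s
  env3 <- env
  env3$samples <- rep(env$samples, 3)
  ep <- simulate_trial_eeg(env3, trf, condition_effects(), tr, 1, lay,
    seed = 1
  )
  expect_equal(dim(ep$data), c(64, 10000))
  expect_equal(ep$fs, 500)
  expect_equal(ep$t0, -5)
  # all component amplitudes zero -> all-zero epoch
  np0 <- default_noise_params(
    tracking = 0, theta = 0, alpha = 0,
    background = 0, source = 0, onset = 0
  )
  ep0 <- simulate_trial_eeg(env, trf, condition_effects(), tr, 1, lay,
    noise_params = np0, seed = 1, window = c(-1, 4)
  )
  expect_equal(max(abs(ep0$data)), 0)
  # stimulus longer than the window is an alignment error
  expect_error(
    simulate_trial_eeg(env3, trf, condition_effects(), tr, 1, lay,
      seed = 1, window = c(-1, 4)
    ),
    "exceeds"
  )
})

test_that("trial simulation is deterministic given its seed", {
  lay <- fix_layout()
  trf <- fix_trf()
  env <- fix_env_nvs()
  tr <- list(prior = "P+", stimulus_type = "NVS", trial_index = 3L)
  e1 <- simulate_trial_eeg(env, trf, paper_like_effects(), tr, 2, lay,
    seed = 42, window = c(-1, 4)
  )
  e2 <- simulate_trial_eeg(env, trf, paper_like_effects(), tr, 2, lay,
    seed = 42, window = c(-1, 4)
  )
  expect_identical(e1$data, e2$data)
  e3 <- simulate_trial_eeg(env, trf, paper_like_effects(), tr, 2, lay,
    seed = 43, window = c(-1, 4)
  )
  expect_false(identical(e1$data, e3$data))
})

test_that("named sub-seeds give independent reproducible substreams", {
  expect_identical(sub_seed(1, "pool"), sub_seed(1, "pool"))
  expect_false(sub_seed(1, "pool") == sub_seed(1, "design"))
  expect_false(sub_seed(1, "pool") == sub_seed(2, "pool"))
  s <- vapply(1:500, function(i) sub_seed(i, "x"), integer(1))
  expect_false(any(duplicated(s)))
  expect_true(all(s > 0 & s < 2^31))
})

test_that("a tiny session is byte-identical under the same seed", {
  pool <- fix_pool5()
  eff <- paper_like_effects()
  args <- list(
    pool = pool, participant_index = 1, effects = eff, seed = 5,
    trials_per_cell = 1, presentations = 2, epoch_window = c(-0.2, 3.7),
    n_iterations = 1, training_duration = 7
  )
  s1 <- do.call(simulate_session, args)
  s2 <- do.call(simulate_session, args)
  expect_identical(s1$design, s2$design)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$pupil, s2$pupil)
  expect_equal(nrow(s1$design), 6) # 6 cells x 1 trial
  expect_length(s1$trials, 6)
  # every trial has its second presentation and clock-aligned epochs
  expect_true(all(grepl("pres2$", names(s1$trials))))
  expect_equal(s1$trials[[1]]$t0, -0.2)
})

test_that("sessions serialize to a text directory", {
  pool <- fix_pool5()
  s <- simulate_session(pool, 1, condition_effects(),
    seed = 9,
    trials_per_cell = 1, presentations = 2, epoch_window = c(-0.2, 3.7),
    n_iterations = 1, training_duration = 7, simulate_pupil_traces = TRUE
  )
  dir <- tempfile("session")
  write_session(s, dir)
  expect_true(file.exists(file.path(dir, "design.tsv")))
  expect_true(file.exists(file.path(dir, "meta.json")))
  d <- readr::read_tsv(file.path(dir, "design.tsv"), show_col_types = FALSE)
  expect_equal(nrow(d), nrow(s$design))
  m <- as.matrix(utils::read.table(file.path(dir, "training_eeg.tsv")))
  expect_equal(dim(m), dim(s$training$eeg$data))
  expect_equal(unname(m[, 1]), unname(s$training$eeg$data[, 1]),
    tolerance = 1e-8
  )
  unlink(dir, recursive = TRUE)
})
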