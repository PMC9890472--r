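# Pupillometry preprocessing.

test_that("blink detection separates blinks from long dropouts", {
  fs <- 300
  x <- rnorm(10 * fs) + 1500
  expect_equal(nrow(detect_blinks(x, fs)), 0)
  # one 200 ms gap
  x2 <- x
  x2[(2 * fs + 1):(2 * fs + 60)] <- NA
  ann <- detect_blinks(x2, fs, t0 = 0)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$type, "blink")
  expect_equal(ann$onset, 2, tolerance = 1 / fs)
  expect_equal(ann$offset, 2.2, tolerance = 1 / fs)
  # a 6 s gap is a dropout, not a blink
  x3 <- rnorm(20 * fs) + 1500
  x3[(3 * fs):(9 * fs)] <- NA
  ann3 <- detect_blinks(x3, fs)
  expect_equal(ann3$type, "dropout")
})

test_that("blink interpolation joins the flanking-window medians", {
  fs <- 300
  # constant trace: gap filled exactly
  x <- rep(7, 5 * fs)
  x[1000:1100] <- NA
  out <- interpolate_blinks(x, detect_blinks(x, fs), fs)
  expect_equal(out, rep(7, 5 * fs))
  # linear ramp: filled values on the ramp
  ramp <- seq(0, 10, length.out = 5 * fs)
  r2 <- ramp
  r2[700:800] <- NA
  out2 <- interpolate_blinks(r2, detect_blinks(r2, fs), fs)
  expect_equal(out2[700:800], ramp[700:800], tolerance = 0.02)
  # hand-set flank medians become the gap endpoints exactly
  y <- rep(0, 2000)
  y[101:130] <- NA # gap of 30 samples
  y[71:100] <- c(rep(2, 15), rep(4, 15)) # pre-flank median 3
  y[131:160] <- c(rep(8, 15), rep(10, 15)) # post-flank median 9
  out3 <- interpolate_blinks(y, detect_blinks(y, fs), fs)
  expect_equal(out3[101], 3)
  expect_equal(out3[130], 9)
  expect_equal(diff(out3[101:130]), rep(6 / 29, 29))
})

test_that("missing flanks widen the search with a warning", {
  fs <- 300
  x <- rep(5, 1000)
  x[101:160] <- NA # blink
  x[71:100] <- NA # empty pre-flank window
  ann <- detect_blinks(x, fs)
  # the two adjacent gaps merge into one run; widen applies when the
  # flank window itself is missing
  expect_equal(nrow(ann), 1)
  out <- interpolate_blinks(x, ann, fs)
  expect_false(anyNA(out))
  expect_equal(unique(out), 5)
})

test_that("filtering and eye averaging meet the frequency specification", {
  fs <- 300
  t <- (0:(10 * fs - 1)) / fs
  slow <- sin(2 * pi * 1 * t)
  fast <- sin(2 * pi * 20 * t)
  out_slow <- filter_and_average(slow, slow, fs)
  out_fast <- filter_and_average(fast, fast, fs)
  interior <- 600:2400
  expect_equal(
    sqrt(mean(out_slow[interior]^2)) / sqrt(0.5), 1,
    tolerance = 0.05
  )
  expect_gt(
    20 * log10(sqrt(mean(slow[interior]^2)) / sqrt(mean(out_fast[interior]^2))),
    20
  )
  # identical eyes: output equals either filtered eye
  expect_equal(filter_and_average(slow, slow, fs), out_slow)
  # eyes offset +/- k around s average to filtered s
  s <- sin(2 * pi * 0.5 * t)
  expect_equal(
    filter_and_average(s + 2, s - 2, fs),
    filter_and_average(s, s, fs),
    tolerance = 1e-9
  )
  expect_warning(
    one <- filter_and_average(slow, rep(NA_real_, length(slow)), fs),
    "using the other eye"
  )
  expect_equal(one, out_slow)
})

test_that("epoching and baselining follow the [-1, 11] s convention", {
  fs <- 300
  x <- rnorm(40 * fs) + 1500
  eps <- epoch_and_baseline(x, fs, t0 = -2, onsets = c(0, 16))
  expect_length(eps, 2)
  expect_equal(length(eps[[1]]$samples), 3600) # 12 s x 300 Hz
  # presentation-1 baseline window mean is zero
  b_idx <- 1:300 # [-1, 0] of epoch 1
  expect_equal(mean(eps[[1]]$samples[b_idx]), 0, tolerance = 1e-9)
  # constant trace: both epochs all-zero
  epc <- epoch_and_baseline(rep(3, 40 * fs), fs, t0 = -2, onsets = c(0, 16))
  expect_equal(max(abs(epc[[1]]$samples)), 0)
  expect_equal(max(abs(epc[[2]]$samples)), 0)
  expect_error(
    epoch_and_baseline(x, fs, t0 = -2, onsets = c(0, 30)),
    "cover"
  )
})

test_that("gap interpolation is accurate for slow traces", {
  # pupil-like traces (energy dominated by < 0.3 Hz components, small
  # ripple up to ~2 Hz) with gaps <= 400 ms: RMS error over the gap
  # <= 10% of trace RMS amplitude. The flank-median convention has an
  # effective ~50 ms lag, so the bound requires slow-dominated content.
  fs <- 300
  t <- (0:(20 * fs - 1)) / fs
  set.seed(11)
  worst <- 0
  for (rep in 1:20) {
    f_slow <- runif(3, 0.05, 0.3)
    f_fast <- runif(1, 1, 1.9)
    x <- colSums(runif(3, 0.5, 1) * sin(outer(2 * pi * f_slow, t) +
      runif(3, 0, 2 * pi))) + 0.05 * sin(2 * pi * f_fast * t)
    gap_start <- sample(3000:4500, 1)
    gap_len <- sample(30:120, 1) # 100-400 ms
    xg <- x
    xg[gap_start:(gap_start + gap_len - 1)] <- NA
    out <- interpolate_blinks(xg, detect_blinks(xg, fs), fs)
    err <- sqrt(mean((out[gap_start:(gap_start + gap_len - 1)] -
      x[gap_start:(gap_start + gap_len - 1)])^2))
    worst <- max(worst, err / sqrt(mean(x^2)))
  }
  expect_lte(worst, 0.10)
})

test_that("simulated traces preprocess end to end", {
  eff <- paper_like_effects()
  tr <- list(prior = "P+", trial_index = 1L)
  trace <- simulate_pupil(tr, eff, seed = 3)
  prep <- preprocess_pupil(trace)
  expect_length(prep$epochs, 2)
  expect_false(anyNA(prep$epochs[[2]]$samples))
  # blink insertion off -> no missing samples
  t2 <- simulate_pupil(tr, eff, seed = 3, blink_rate = 0)
  expect_false(anyNA(t2$left) || anyNA(t2$right))
  # neutral gains: dilation equal across priors within Monte Carlo error
  eff0 <- condition_effects()
  mean_dil <- function(prior) {
    mean(vapply(1:30, function(i) {
      tr <- list(prior = prior, trial_index = i)
      p <- preprocess_pupil(simulate_pupil(tr, eff0, seed = 400 + i))
      mean(p$epochs[[2]]$samples)
    }, numeric(1)))
  }
  expect_equal(mean_dil("P+"), mean_dil("P0"), tolerance = 12)
})
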