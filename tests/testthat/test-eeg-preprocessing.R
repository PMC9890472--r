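# Deterministic EEG conditioning: epoching, filtering, channel
# interpolation, re-referencing, decoder-ready resampling.

toy_recording <- function(n_ch = 6, dur = 60, fs = 500, seed = 1) {
  set.seed(seed)
  eeg_epoch(matrix(rnorm(n_ch * dur * fs), n_ch), fs,
    t0 = 0,
    channels = paste0("ch", seq_len(n_ch))
  )
}

test_that("epoching cuts 20 s windows of 10,000 samples, demeaned", {
  rec <- toy_recording()
  rec$data[2, ] <- rec$data[2, ] + 7 # constant offset channel
  eps <- epoch_eeg(rec, onsets = c(10, 35), window = c(-5, 15))
  expect_length(eps, 2)
  expect_equal(ncol(eps[[1]]$data), 10000)
  expect_equal(eps[[1]]$t0, -5)
  expect_equal(max(abs(rowMeans(eps[[1]]$data))), 0, tolerance = 1e-12)
  expect_error(
    epoch_eeg(rec, onsets = 58, window = c(-5, 15)),
    "outside the recording"
  )
  # design-order epochs for a 96-onset list
  rec2 <- toy_recording(n_ch = 2, dur = 2000)
  on96 <- seq(10, by = 20, length.out = 96)
  expect_length(epoch_eeg(rec2, on96, window = c(-5, 15)), 96)
})

test_that("band-pass and notch filters meet their specifications", {
  fs <- 500
  t <- (0:9999) / fs
  mk <- function(x) eeg_epoch(matrix(x, 1), fs, t0 = 0, channels = "Cz")
  # DC offset removed by the 1 Hz high-pass (residual mean)
  dc <- filter_eeg(mk(rep(5, length(t))))
  expect_lt(abs(mean(dc$data)) / 5, 1e-3)
  # 50 Hz line noise removed by the DFT notch
  line <- filter_eeg(mk(sin(2 * pi * 50 * t)))
  expect_lt(sqrt(mean(line$data^2)), 0.01 * sqrt(0.5))
  # 10 Hz passband gain within +/- 5% (interior samples)
  ten <- filter_eeg(mk(sin(2 * pi * 10 * t)))
  interior <- 1000:9000
  gain <- sqrt(mean(ten$data[1, interior]^2)) / sqrt(0.5)
  expect_lt(abs(gain - 1), 0.05)
  expect_error(
    filter_eeg(eeg_epoch(matrix(rnorm(200), 1), 200)),
    "too low"
  )
})

test_that("bad channels are replaced by the inverse-distance neighbor mean", {
  lay <- fix_layout()
  n <- 500
  set.seed(3)
  data <- matrix(rnorm(64 * n), 64, dimnames = list(lay$channel, NULL))
  ep <- eeg_epoch(data, 500, t0 = 0, channels = lay$channel)
  out <- interpolate_bad_channels(ep, "Cz", lay)
  d <- popout:::layout_distances(lay)
  nb <- lay$channel[d["Cz", ] < 0.04 & lay$channel != "Cz"]
  w <- 1 / d["Cz", nb]
  oracle <- colSums(data[nb, ] * w) / sum(w)
  expect_equal(out$data["Cz", ], oracle, tolerance = 1e-12)
  # good channels untouched; no bad channels = identity
  expect_equal(out$data["Pz", ], data["Pz", ])
  expect_equal(interpolate_bad_channels(ep, character(0), lay)$data, data)
  # identical neighbors reproduce the common signal exactly
  s <- rnorm(n)
  data2 <- data
  data2[nb, ] <- matrix(s, length(nb), n, byrow = TRUE)
  ep2 <- eeg_epoch(data2, 500, channels = lay$channel)
  expect_equal(interpolate_bad_channels(ep2, "Cz", lay)$data["Cz", ], s)
})

test_that("isolated bad channels are rejected with their name", {
  lay <- fix_layout()[c(1, 30, 64), ] # Fp1, Cz-ish, O2: mutually distant
  ep <- eeg_epoch(matrix(rnorm(300), 3), 500, channels = lay$channel)
  expect_error(
    interpolate_bad_channels(ep, lay$channel[1], lay),
    lay$channel[1]
  )
})

test_that("re-referencing schemes behave as defined", {
  lay <- fix_layout()
  set.seed(5)
  data <- matrix(rnorm(64 * 200), 64, dimnames = list(lay$channel, NULL))
  ep <- eeg_epoch(data, 500, channels = lay$channel)
  avg <- rereference(ep, "common_average")
  expect_lt(max(abs(colMeans(avg$data))), 1e-12)
  # idempotence
  expect_equal(rereference(avg, "common_average")$data, avg$data)
  # identical mastoid signal s: output = input - s
  s <- rnorm(200)
  data2 <- data
  data2[c("TP9", "TP10"), ] <- matrix(s, 2, 200, byrow = TRUE)
  ep2 <- eeg_epoch(data2, 500, channels = lay$channel)
  mast <- rereference(ep2, "linked_mastoids")
  expect_equal(mast$data["Cz", ], data2["Cz", ] - s)
  ep3 <- eeg_epoch(data[1:10, ], 500, channels = lay$channel[1:10])
  expect_error(rereference(ep3, "linked_mastoids"), "missing")
})

test_that("decoder-ready transform selects the 2-8 Hz band at 100 Hz", {
  fs <- 500
  t <- (-2 * fs):(13 * fs - 1) / fs
  mk <- function(f) {
    eeg_epoch(
      matrix(rep(sin(2 * pi * f * t), 4), 4, byrow = TRUE) +
        matrix(rnorm(4 * length(t), sd = 1e-9), 4),
      fs,
      t0 = -2, channels = paste0("ch", 1:4)
    )
  }
  # 4-channel epochs are common-average referenced, so use channel pairs
  # with opposite signs to survive the reference
  mk2 <- function(f) {
    x <- sin(2 * pi * f * t)
    eeg_epoch(rbind(x, -x, 0.5 * x, -0.5 * x), fs,
      t0 = -2,
      channels = paste0("ch", 1:4)
    )
  }
  in5 <- prepare_for_decoding(mk2(5), 10.5)
  in1 <- prepare_for_decoding(mk2(1), 10.5)
  expect_equal(in5$fs, 100)
  expect_equal(ncol(in5$data), 1050, tolerance = 1)
  interior <- 100:950
  a5 <- sqrt(mean(in5$data[1, interior]^2))
  a1 <- sqrt(mean(in1$data[1, interior]^2))
  expect_gt(a5 / sqrt(0.5), 0.9) # 5 Hz retained
  expect_gt(20 * log10(a5 / a1), 20) # 1 Hz attenuated >= 20 dB
  # zero in, zero out
  z <- prepare_for_decoding(
    eeg_epoch(matrix(0, 4, length(t)), fs, t0 = -2),
    10.5
  )
  expect_equal(max(abs(z$data)), 0)
  expect_error(
    prepare_for_decoding(eeg_epoch(matrix(0, 4, 1000), fs, t0 = -2), 10.5),
    "cover"
  )
})

test_that("the preprocessing chain is linear", {
  fs <- 500
  set.seed(8)
  a <- matrix(rnorm(4 * 6000), 4)
  b <- matrix(rnorm(4 * 6000), 4)
  mk <- function(m) eeg_epoch(m, fs, t0 = -1, channels = paste0("ch", 1:4))
  chain <- function(m) {
    out <- prepare_for_decoding(filter_eeg(mk(m)), 10)
    out$data
  }
  lhs <- chain(a + b)
  rhs <- chain(a) + chain(b)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  # channel order and names survive
  out <- filter_eeg(mk(a))
  expect_identical(out$channels, paste0("ch", 1:4))
})
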