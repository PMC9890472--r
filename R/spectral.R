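# Time-frequency power (Hanning taper), band-averaged log power, and
# induced (non-phase-locked) oscillatory profiles.

#' Short-time Hanning-taper time-frequency decomposition
#'
#' Power at 1 Hz resolution (1-30 Hz by default) and 100 ms steps, using a
#' 1 s Hanning taper. Power is scaled so a unit-amplitude sinusoid at a bin
#' center yields power 1 (single-sided amplitude-squared convention).
#'
#' @param epoch An [eeg_epoch()].
#' @param freqs Frequencies in Hz; must be multiples of `1/taper_len`.
#' @param taper_len Taper length in seconds.
#' @param step Time step between window centers in seconds.
#' @param time_range Optional two-element range for the window centers;
#'   defaults to every center the epoch can support.
#' @return An object of class `tfr`: `power` (channel x frequency x time),
#'   `freqs`, `times` (window centers, s), `channels`.
#' @export
tf_decompose <- function(epoch, freqs = 1:30, taper_len = 1, step = 0.1,
                         time_range = NULL) {
  fs <- epoch$fs
  L <- round(taper_len * fs)
  half <- taper_len / 2
  t_end <- epoch$t0 + (ncol(epoch$data) - 1) / fs
  lo <- epoch$t0 + half
  hi <- t_end - half
  if (!is.null(time_range)) {
    lo <- max(lo, time_range[1])
    hi <- min(hi, time_range[2])
  }
  if (hi < lo) {
    abort("epoch too short for the requested time-frequency windows")
  }
  centers <- seq(ceiling(lo / step) * step, hi + 1e-9, by = step)
  bins <- freqs * taper_len
  if (any(abs(bins - round(bins)) > 1e-9)) {
    abort("`freqs` must be integer multiples of 1/taper_len")
  }
  bins <- as.integer(round(bins)) + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 0.5) / L)
  wsum <- sum(w)
  n_ch <- nrow(epoch$data)
  pow <- array(0, c(n_ch, length(freqs), length(centers)))
  for (i in seq_along(centers)) {
    s <- round((centers[i] - half - epoch$t0) * fs) + 1L
    seg <- t(epoch$data[, s:(s + L - 1L), drop = FALSE]) * w
    spec <- mvfft(seg)[bins, , drop = FALSE]
    pow[, , i] <- t((2 * Mod(spec) / wsum)^2)
  }
  structure(
    list(
      power = pow, freqs = freqs, times = centers,
      channels = epoch$channels, taper_len = taper_len
    ),
    class = "tfr"
  )
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf(
    "<tfr> %d channels x %d freqs (%g-%g Hz) x %d times ([%.2f, %.2f] s)\n",
    dim(x$power)[1], dim(x$power)[2], min(x$freqs), max(x$freqs),
    dim(x$power)[3], min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Canonical frequency-band definitions
#'
#' Delta 1-3, theta 4-9, alpha 10-15 and beta 16-30 Hz.
#'
#' @return Named list of two-element frequency ranges (Hz).
#' @export
power_bands <- function() {
  list(
    delta = c(1, 3), theta = c(4, 9), alpha = c(10, 15), beta = c(16, 30)
  )
}

#' Band-averaged log power from a time-frequency decomposition
#'
#' Averages power over the analysis window and the band's frequency bins,
#' then log10-transforms, one value per channel.
#'
#' @param tfr A [tf_decompose()] result.
#' @param band Two-element frequency range in Hz, or the name of a band
#'   from [power_bands()].
#' @param window Analysis window for the time-bin centers, seconds.
#' @return A tibble with columns `channel`, `band`, `log_power`.
#' @export
band_average <- function(tfr, band, window = c(0.5, 3)) {
  band_name <- if (is.character(band)) band else paste0(band[1], "-", band[2], "Hz")
  if (is.character(band)) band <- power_bands()[[band]]
  f_idx <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  t_idx <- which(tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9)
  if (!length(f_idx) || !length(t_idx)) {
    abort("empty frequency band or time window")
  }
  m <- apply(tfr$power[, f_idx, t_idx, drop = FALSE], 1, mean)
  tibble::tibble(
    channel = tfr$channels, band = band_name,
    log_power = log10(m)
  )
}

#' Time-resolved induced (non-phase-locked) power profile
#'
#' The intertrial-variance estimate of induced activity for one condition
#' cell: each epoch is band-pass filtered (one-pass zero-phase FIR), the
#' cell-mean evoked waveform is subtracted, waveforms are squared and
#' log10-transformed (with a small floor), averaged over trials, smoothed
#' with a 500 ms moving average, and downsampled to 10 Hz. No baseline
#' scaling is applied.
#'
#' @param epochs List of [eeg_epoch()] objects from one condition cell
#'   (same shape); at least 2.
#' @param band Two-element frequency range in Hz.
#' @param fs_out Output rate (10 Hz).
#' @param smooth Moving-average window in seconds.
#' @param log_floor Floor added before the log of squared amplitudes.
#' @return An object of class `induced_profile`: `values` (channel x
#'   time), `times`, `band`, `channels`, `n_trials`.
#' @export
induced_profile <- function(epochs, band, fs_out = 10, smooth = 0.5,
                            log_floor = 1e-20) {
  if (length(epochs) < 2) {
    abort("induced power needs at least 2 epochs per cell (evoked subtraction)")
  }
  fs <- epochs[[1]]$fs
  n_taps <- 2L * round(1.5 * fs / band[1]) + 1L # 3 cycles of the low edge
  h <- fir_design(fs, low = band[1], high = band[2], n_taps = n_taps)
  filt <- lapply(epochs, function(e) apply_fir(t(e$data), h, passes = 1))
  evoked <- Reduce(`+`, filt) / length(filt)
  acc <- 0
  for (f in filt) acc <- acc + log10((f - evoked)^2 + log_floor)
  avg <- acc / length(filt)
  k <- round(smooth * fs)
  kern <- rep(1 / k, k)
  sm <- apply(avg, 2, function(col) {
    as.numeric(stats::filter(col, kern, sides = 2))
  })
  dec <- round(fs / fs_out)
  idx <- seq(1L, nrow(sm), by = dec)
  times <- epoch_times(epochs[[1]])[idx]
  keep <- complete.cases(sm[idx, , drop = FALSE])
  structure(
    list(
      values = t(sm[idx[keep], , drop = FALSE]),
      times = times[keep], band = band,
      channels = epochs[[1]]$channels, n_trials = length(epochs)
    ),
    class = "induced_profile"
  )
}

#' @export
print.induced_profile <- function(x, ...) {
  cat(sprintf(
    "<induced_profile> %d channels x %d bins @ [%.1f, %.1f] s, band %g-%g Hz (%d trials)\n",
    nrow(x$values), ncol(x$values), min(x$times), max(x$times),
    x$band[1], x$band[2], x$n_trials
  ))
  invisible(x)
}
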