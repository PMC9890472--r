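#' Construct an EEG epoch
#'
#' A channel-by-sample matrix with its sampling rate, the time of the first
#' sample relative to stimulus onset, channel names and optional trial
#' metadata.
#'
#' @param data Channel x sample numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample in seconds relative to stimulus onset.
#' @param channels Channel names (defaults to rownames of `data`).
#' @param meta Optional named list of trial metadata.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, t0 = 0, channels = rownames(data),
                      meta = list()) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, t0 = t0, channels = channels, meta = meta),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf(
    "<eeg_epoch> %d channels x %d samples @ %g Hz, t = [%.2f, %.2f] s\n",
    nrow(x$data), ncol(x$data), x$fs, x$t0,
    x$t0 + (ncol(x$data) - 1) / x$fs
  ))
  invisible(x)
}

epoch_times <- function(epoch) {
  epoch$t0 + (seq_len(ncol(epoch$data)) - 1) / epoch$fs
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Epochs default to the 20 s window from 5 s before to 15 s after each
#' stimulus onset. Every channel is demeaned per epoch (epochs centered on
#' zero).
#'
#' @param recording An [eeg_epoch()] holding the continuous recording
#'   (`t0` gives its clock origin).
#' @param onsets Stimulus onset times in seconds (same clock).
#' @param window Two-element epoch window in seconds relative to onset.
#' @param demean Center each channel within the epoch.
#' @return A list of [eeg_epoch()] objects in onset order.
#' @export
epoch_eeg <- function(recording, onsets, window = c(-5, 15), demean = TRUE) {
  fs <- recording$fs
  n <- ncol(recording$data)
  len <- round(diff(window) * fs)
  lapply(seq_along(onsets), function(i) {
    start <- round((onsets[i] + window[1] - recording$t0) * fs) + 1L
    if (start < 1L || start + len - 1L > n) {
      abort(sprintf(
        "epoch %d ([%g, %g] s around onset %g s) falls outside the recording",
        i, window[1], window[2], onsets[i]
      ))
    }
    d <- recording$data[, start:(start + len - 1L), drop = FALSE]
    if (demean) d <- d - rowMeans(d)
    eeg_epoch(d, fs,
      t0 = window[1], channels = recording$channels,
      meta = c(recording$meta, list(onset = onsets[i]))
    )
  })
}

#' Band-pass and notch filter an epoch
#'
#' Two-pass 4th-order Butterworth high-pass (1 Hz) and low-pass (125 Hz)
#' filters, followed by a discrete-Fourier-transform notch that removes the
#' 50 and 100 Hz line components.
#'
#' @param epoch An [eeg_epoch()].
#' @param high_pass,low_pass Cutoffs in Hz.
#' @param notch Frequencies (Hz) removed by the DFT notch.
#' @return The filtered epoch.
#' @export
filter_eeg <- function(epoch, high_pass = 1, low_pass = 125,
                       notch = c(50, 100)) {
  if (epoch$fs <= 2 * low_pass) {
    abort(sprintf(
      "sampling rate %g Hz is too low for a %g Hz low-pass", epoch$fs, low_pass
    ))
  }
  x <- t(epoch$data)
  # centering before filtering keeps the high-pass edge transients small
  x <- sweep(x, 2, colMeans(x))
  x <- butter_filtfilt(x, epoch$fs, order = 4, cutoff = high_pass, type = "high")
  x <- butter_filtfilt(x, epoch$fs, order = 4, cutoff = low_pass, type = "low")
  if (length(notch)) x <- dft_notch(x, epoch$fs, notch)
  epoch$data <- t(x)
  rownames(epoch$data) <- epoch$channels
  epoch
}

#' Interpolate bad channels by inverse-distance weighting
#'
#' Each bad channel is replaced by the inverse-distance-weighted mean of
#' its good neighbors within `radius`; good channels are untouched.
#'
#' @param epoch An [eeg_epoch()].
#' @param bad_channels Character vector of channel names.
#' @param layout Sensor layout from [channel_layout()].
#' @param radius Neighborhood radius in meters.
#' @return The repaired epoch.
#' @export
interpolate_bad_channels <- function(epoch, bad_channels, layout,
                                     radius = 0.040) {
  if (!length(bad_channels)) {
    return(epoch)
  }
  missing <- setdiff(bad_channels, epoch$channels)
  if (length(missing)) {
    abort(paste0("unknown bad channel(s): ", paste(missing, collapse = ", ")))
  }
  d <- layout_distances(layout)[epoch$channels, epoch$channels]
  good <- setdiff(epoch$channels, bad_channels)
  out <- epoch$data
  for (bc in bad_channels) {
    nb <- good[d[bc, good] < radius]
    if (length(nb) < 2) {
      abort(sprintf(
        "bad channel %s has fewer than 2 good neighbors within %.0f mm",
        bc, radius * 1000
      ))
    }
    w <- 1 / d[bc, nb]
    out[bc, ] <- colSums(epoch$data[nb, , drop = FALSE] * w) / sum(w)
  }
  epoch$data <- out
  epoch
}

#' Re-reference an epoch
#'
#' `common_average` subtracts the instantaneous mean over all channels;
#' `linked_mastoids` subtracts the mean of the two mastoid channels.
#'
#' @param epoch An [eeg_epoch()].
#' @param scheme `"common_average"` or `"linked_mastoids"`.
#' @param mastoids Mastoid channel names.
#' @return The re-referenced epoch.
#' @export
rereference <- function(epoch, scheme = c("common_average", "linked_mastoids"),
                        mastoids = c("TP9", "TP10")) {
  scheme <- match.arg(scheme)
  if (scheme == "common_average") {
    ref <- colMeans(epoch$data)
  } else {
    if (!all(mastoids %in% epoch$channels)) {
      abort(paste0(
        "mastoid channel(s) missing: ",
        paste(setdiff(mastoids, epoch$channels), collapse = ", ")
      ))
    }
    ref <- colMeans(epoch$data[mastoids, , drop = FALSE])
  }
  epoch$data <- sweep(epoch$data, 2, ref)
  epoch
}

#' Prepare an epoch for envelope decoding
#'
#' The decoder-ready transform: common-average reference, 2-8 Hz two-pass
#' FIR band-pass, resampling to 100 Hz, and trimming to exactly the
#' stimulus span `[0, stimulus_duration]`. The sample count is reconciled
#' with the envelope's by truncation to the requested length.
#'
#' @param epoch An [eeg_epoch()] covering `[0, stimulus_duration]`.
#' @param stimulus_duration Stimulus duration in seconds.
#' @param band Pass band in Hz.
#' @param target_fs Output rate (100 Hz).
#' @return An [eeg_epoch()] at `target_fs` with `t0 = 0`.
#' @export
prepare_for_decoding <- function(epoch, stimulus_duration, band = c(2, 8),
                                 target_fs = 100) {
  t_end <- epoch$t0 + ncol(epoch$data) / epoch$fs
  if (epoch$t0 > 1e-9 || t_end < stimulus_duration - 1e-9) {
    abort(sprintf(
      "epoch [%.2f, %.2f] s does not cover the stimulus span [0, %.2f] s",
      epoch$t0, t_end, stimulus_duration
    ))
  }
  epoch <- rereference(epoch, "common_average")
  x <- envelope_bandpass(t(epoch$data), epoch$fs, band)
  x <- resample_sig(x, epoch$fs, target_fs)
  offset <- round(-epoch$t0 * target_fs)
  n_keep <- round(stimulus_duration * target_fs)
  n_keep <- min(n_keep, nrow(x) - offset)
  x <- x[(offset + 1):(offset + n_keep), , drop = FALSE]
  eeg_epoch(t(x), target_fs,
    t0 = 0, channels = epoch$channels,
    meta = epoch$meta
  )
}
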