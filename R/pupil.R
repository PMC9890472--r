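# Pupillometry preprocessing: blink detection and interpolation, low-pass
# filtering, eye averaging, epoching, baseline correction. Pupil size is
# in arbitrary units throughout.

#' Detect blinks in a single-eye pupil trace
#'
#' Maximal runs of missing samples with duration at most `max_duration`
#' (5 s) are blinks; longer runs are flagged as dropouts and excluded from
#' interpolation.
#'
#' @param samples Numeric vector with `NA` marking signal interruptions.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s).
#' @param max_duration Maximum blink duration in seconds.
#' @return A tibble with columns `onset`, `offset` (seconds), `duration`,
#'   and `type` (`"blink"` or `"dropout"`).
#' @export
detect_blinks <- function(samples, fs, t0 = 0, max_duration = 5) {
  r <- rle(is.na(samples))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap <- which(r$values)
  if (!length(gap)) {
    return(tibble::tibble(
      onset = numeric(), offset = numeric(),
      duration = numeric(), type = character()
    ))
  }
  onset <- t0 + (starts[gap] - 1) / fs
  offset <- t0 + ends[gap] / fs
  duration <- offset - onset
  tibble::tibble(
    onset = onset, offset = offset, duration = duration,
    type = ifelse(duration <= max_duration, "blink", "dropout")
  )
}

#' Interpolate blinks in a single-eye pupil trace
#'
#' Each blink gap is replaced by the line joining the median of the valid
#' signal in the 100 ms window before blink onset to the median in the
#' 100 ms window after blink offset; the first and last interpolated
#' samples equal those medians exactly. If a flanking window holds no
#' valid sample the search widens to the nearest valid 100 ms window (with
#' a warning). Dropouts (gaps longer than the blink limit) are left
#' missing.
#'
#' @param samples Numeric vector with `NA` gaps.
#' @param annotations Annotations from [detect_blinks()].
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s).
#' @param flank Flanking-window length in seconds.
#' @return The trace with blink gaps filled.
#' @export
interpolate_blinks <- function(samples, annotations, fs, t0 = 0,
                               flank = 0.1) {
  n <- length(samples)
  flank_n <- max(1L, round(flank * fs))
  flank_median <- function(edge_idx, direction) {
    # direction -1: window ending just before edge; +1: starting at edge
    shift <- 0L
    repeat {
      if (direction < 0) {
        hi <- edge_idx - 1L - shift
        lo <- hi - flank_n + 1L
      } else {
        lo <- edge_idx + shift
        hi <- lo + flank_n - 1L
      }
      if (hi < 1L || lo > n) {
        return(NA_real_)
      }
      win <- samples[max(lo, 1L):min(hi, n)]
      if (any(!is.na(win))) {
        if (shift > 0L) {
          warn("flanking window had no valid samples; widened the search")
        }
        return(median(win, na.rm = TRUE))
      }
      shift <- shift + flank_n
    }
  }
  blinks <- annotations[annotations$type == "blink", , drop = FALSE]
  for (i in seq_len(nrow(blinks))) {
    i1 <- round((blinks$onset[i] - t0) * fs) + 1L
    i2 <- round((blinks$offset[i] - t0) * fs)
    i1 <- max(i1, 1L)
    i2 <- min(i2, n)
    m1 <- flank_median(i1, -1)
    m2 <- flank_median(i2 + 1L, +1)
    if (is.na(m1)) m1 <- m2
    if (is.na(m2)) m2 <- m1
    g <- i2 - i1 + 1L
    samples[i1:i2] <- if (g == 1L) {
      (m1 + m2) / 2
    } else {
      m1 + (m2 - m1) * (seq_len(g) - 1) / (g - 1)
    }
  }
  samples
}

#' Low-pass filter both eyes and average them
#'
#' Two-pass 4th-order Butterworth low-pass at 6 Hz per eye, then the
#' arithmetic mean of the two eyes. If one eye is entirely missing the
#' other is used alone (with a warning).
#'
#' @param left,right Gap-free numeric traces (one per eye).
#' @param fs Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz).
#' @return The averaged, filtered trace.
#' @export
filter_and_average <- function(left, right, fs, cutoff = 6) {
  eyes <- list(left = left, right = right)
  present <- !vapply(eyes, function(e) all(is.na(e)), logical(1))
  if (!any(present)) abort("both eyes are missing")
  if (!all(present)) {
    warn(paste0("eye '", names(eyes)[!present], "' missing; using the other eye"))
    eyes <- eyes[present]
  }
  if (any(vapply(eyes, anyNA, logical(1)))) {
    abort("traces must be gap-free; interpolate blinks first")
  }
  filt <- lapply(eyes, function(e) {
    butter_filtfilt(e, fs, order = 4, cutoff = cutoff, type = "low")
  })
  Reduce(`+`, filt) / length(filt)
}

#' Epoch a pupil trace around both presentations and baseline-correct
#'
#' Cuts one `[-1, 11]` s epoch per presentation and subtracts the mean
#' pupil size in the second before the first presentation from both.
#'
#' @param samples Preprocessed (averaged) trace.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s, in the trial clock).
#' @param onsets Two presentation onsets (s).
#' @param window Epoch window around each onset (s).
#' @param baseline_window Baseline window relative to the first onset (s).
#' @return A list of two `pupil_epoch` objects (fields `samples`, `fs`,
#'   `t0`, `presentation`, `baseline`).
#' @export
epoch_and_baseline <- function(samples, fs, t0, onsets, window = c(-1, 11),
                               baseline_window = c(-1, 0)) {
  n <- length(samples)
  cut_idx <- function(onset) {
    i1 <- round((onset + window[1] - t0) * fs) + 1L
    i2 <- i1 + round(diff(window) * fs) - 1L
    if (i1 < 1L || i2 > n) {
      abort(sprintf(
        "pupil trace does not cover [%g, %g] s around onset %g s",
        window[1], window[2], onset
      ))
    }
    i1:i2
  }
  b1 <- round((onsets[1] + baseline_window[1] - t0) * fs) + 1L
  b2 <- round((onsets[1] + baseline_window[2] - t0) * fs)
  if (b1 < 1L || b2 > n) abort("trace does not cover the baseline window")
  baseline <- mean(samples[b1:b2])
  lapply(1:2, function(p) {
    structure(
      list(
        samples = samples[cut_idx(onsets[p])] - baseline,
        fs = fs, t0 = window[1], presentation = p, baseline = baseline
      ),
      class = "pupil_epoch"
    )
  })
}

#' Preprocess a simulated two-eye pupil trace end to end
#'
#' Blink detection and interpolation per eye, 6 Hz low-pass, eye
#' averaging, epoching around both presentations, and baseline correction.
#' Trials containing a dropout (gap above the blink limit) are flagged.
#'
#' @param trace A `pupil_trace` from [simulate_pupil()].
#' @param window,baseline_window See [epoch_and_baseline()].
#' @return A list with `epochs` (two `pupil_epoch`s), `dropout` (logical),
#'   and `annotations` per eye.
#' @export
preprocess_pupil <- function(trace, window = c(-1, 11),
                             baseline_window = c(-1, 0)) {
  ann <- lapply(
    list(left = trace$left, right = trace$right),
    detect_blinks,
    fs = trace$fs, t0 = trace$t0
  )
  eyes <- purrr::imap(
    list(left = trace$left, right = trace$right),
    function(e, nm) interpolate_blinks(e, ann[[nm]], trace$fs, trace$t0)
  )
  dropout <- any(vapply(ann, function(a) any(a$type == "dropout"), logical(1)))
  if (dropout) {
    # dropouts are never blink-interpolated; bridge them linearly only so
    # the numeric pipeline can continue -- the trial stays flagged for
    # exclusion from analysis
    eyes <- lapply(eyes, function(e) {
      if (anyNA(e) && any(!is.na(e))) {
        idx <- seq_along(e)
        e <- approx(idx[!is.na(e)], e[!is.na(e)], xout = idx, rule = 2)$y
      }
      e
    })
  }
  avg <- filter_and_average(eyes$left, eyes$right, trace$fs)
  epochs <- epoch_and_baseline(
    avg, trace$fs, trace$t0, trace$onsets,
    window, baseline_window
  )
  list(epochs = epochs, dropout = dropout, annotations = ann)
}
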