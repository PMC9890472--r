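# Shared signal-processing primitives. EEG matrices are channel x sample
# throughout the package; these helpers work on sample-major matrices
# (samples in rows) internally because mvfft operates on columns.

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Design a windowed-sinc FIR filter
#'
#' Hamming-windowed sinc design. `low`/`high` give the pass-band edges in Hz;
#' use `low = NULL` for a low-pass and `high = NULL` for a high-pass filter.
#' The number of taps is forced odd so the filter is exactly symmetric
#' (linear phase, integer group delay).
#'
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges in Hz (either may be `NULL`).
#' @param n_taps Filter length in samples; forced odd.
#' @return Numeric vector of filter coefficients.
#' @export
fir_design <- function(fs, low = NULL, high = NULL, n_taps) {
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) / 2L
  k <- seq(-m, m)
  sinc <- function(fc) {
    x <- 2 * fc / fs
    ifelse(k == 0, x, x * sin(pi * x * k) / (pi * x * k))
  }
  h <- if (is.null(low) && !is.null(high)) {
    sinc(high)
  } else if (!is.null(low) && is.null(high)) {
    delta <- as.numeric(k == 0)
    delta - sinc(low)
  } else if (!is.null(low) && !is.null(high)) {
    sinc(high) - sinc(low)
  } else {
    abort("fir_design(): at least one of `low`, `high` must be given")
  }
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h * w
}

# FFT convolution of each column of `x` with symmetric kernel `h`,
# delay-compensated so each pass is zero phase. Reflection padding at the
# edges. `passes = 2` squares the magnitude response (2-pass filtering).
apply_fir <- function(x, h, passes = 2) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  lh <- length(h)
  delay <- (lh - 1L) / 2L
  pad <- min(lh, n - 1L)
  for (p in seq_len(passes)) {
    top <- x[pmin(pad + 1L, n):2L, , drop = FALSE]
    bot <- x[(n - 1L):max(n - pad, 1L), , drop = FALSE]
    xp <- rbind(top, x, bot)
    np <- nrow(xp)
    nfft <- next_pow2(np + lh - 1L)
    H <- fft(c(h, numeric(nfft - lh)))
    X <- mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
    y <- Re(mvfft(X * H, inverse = TRUE)) / nfft
    x <- y[(nrow(top) + delay + 1L):(nrow(top) + delay + n), , drop = FALSE]
  }
  if (vec) drop(x) else x
}

# Discrete-Fourier-transform notch: least-squares fit and removal of the
# sine/cosine pair at each target frequency over the whole epoch.
dft_notch <- function(x, fs, freqs) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  t <- (seq_len(n) - 1) / fs
  basis <- do.call(cbind, lapply(freqs, function(f) {
    cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  }))
  beta <- qr.solve(basis, x)
  out <- x - basis %*% beta
  if (vec) drop(out) else out
}

# Two-pass Butterworth via signal::butter + signal::filtfilt, column-wise.
butter_filtfilt <- function(x, fs, order, cutoff, type) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  out <- matrix(out, nrow = nrow(x))
  if (vec) drop(out) else out
}

# One-pass (causal) Butterworth, column-wise.
butter_filter <- function(x, fs, order, cutoff, type) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  out <- apply(x, 2, function(col) as.numeric(signal::filter(bf, col)))
  out <- matrix(out, nrow = nrow(x))
  if (vec) drop(out) else out
}

#' Resample a signal with anti-alias filtering
#'
#' Windowed-sinc low-pass at 0.45 of the target rate (when decimating)
#' followed by linear interpolation onto the target time grid. The output
#' length is `round(n * fs_out / fs_in)`.
#'
#' @param x Numeric vector or sample-by-channel matrix.
#' @param fs_in,fs_out Input and output sampling rates (Hz).
#' @return Resampled signal of the same shape class as `x`.
#' @export
resample_sig <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (fs_out < fs_in) {
    cutoff <- 0.45 * fs_out
    n_taps <- max(31L, 2L * ceiling(2 * fs_in / cutoff) + 1L)
    h <- fir_design(fs_in, high = cutoff, n_taps = n_taps)
    x <- apply_fir(x, h, passes = 1)
  }
  m <- round(n * fs_out / fs_in)
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- (seq_len(m) - 1) / fs_out
  out <- apply(x, 2, function(col) {
    approx(t_in, col, xout = t_out, rule = 2)$y
  })
  out <- matrix(out, nrow = m)
  if (vec) drop(out) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1/f ("pink") noise via spectral shaping; one column per channel.
pink_noise <- function(n, n_chan = 1, exponent = 1) {
  nfft <- next_pow2(n)
  f <- c(1, seq_len(nfft / 2), rev(seq_len(nfft / 2 - 1)))
  amp <- f^(-exponent / 2)
  amp[1] <- 0
  out <- matrix(0, n, n_chan)
  for (ch in seq_len(n_chan)) {
    phase <- runif(nfft, 0, 2 * pi)
    spec <- amp * exp(1i * phase)
    x <- Re(fft(spec, inverse = TRUE))
    x <- x[seq_len(n)]
    out[, ch] <- x / sd(x)
  }
  out
}

# Band-limited Gaussian noise (two-pass Butterworth band-pass), column-major.
band_noise <- function(n, n_chan, fs, low, high) {
  x <- matrix(rnorm(n * n_chan), n, n_chan)
  y <- butter_filtfilt(x, fs, order = 3, cutoff = c(low, high), type = "pass")
  sds <- apply(y, 2, sd)
  sweep(y, 2, pmax(sds, .Machine$double.eps), "/")
}

rms <- function(x) sqrt(mean(x^2))

# single-pass IIR via stats::filter (C code): MA part as convolution,
# AR part as recursion. Zero initial conditions. Columns of a matrix are
# filtered independently in one call.
iir_pass <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  nb <- length(b)
  xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
  v <- stats::filter(xp, b, "convolution", sides = 1)
  v <- v[nb:nrow(xp), , drop = FALSE]
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1] / a[1], "recursive") / a[1]
  }
  v <- matrix(as.numeric(v), ncol = ncol(x))
  if (vec) drop(v) else v
}

# forward-backward IIR with reflection padding (zero-phase, squared
# magnitude response); fast replacement for two-pass Butterworth filtering
# of long vectors/matrices.
iir_filtfilt <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  top <- 2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) -
    x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) -
    x[(n - 1L):(n - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- iir_pass(b, a, xp)
  y <- iir_pass(b, a, y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- y[(pad + 1L):(pad + n), , drop = FALSE]
  if (vec) drop(y) else y
}
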