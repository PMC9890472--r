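# Backward (stimulus-reconstruction) temporal-response-function decoder:
# a ridge-regularized linear map from multichannel lagged EEG to the 2-8 Hz
# auditory envelope. The envelope at time t is predicted from EEG at
# t .. t+300 ms (post-stimulus EEG carries the response to the stimulus).

#' Build the lagged design matrix for backward decoding
#'
#' Column `(c, l)` holds EEG channel `c` advanced by lag `l` relative to
#' the envelope: `X[t, (c, l)] = eeg[c, t + l]`, zero-padded at the end.
#' Columns are ordered channel-major: all lags of channel 1, then all lags
#' of channel 2, and so on; this order is stable and matches the
#' `weights` matrix layout of [train_decoder()].
#'
#' @param eeg An [eeg_epoch()] at the envelope rate (100 Hz).
#' @param lags_ms Lags in milliseconds (0 to 300 in steps of 10; 31 lags).
#' @return A samples x (channels * lags) numeric matrix.
#' @export
lag_design <- function(eeg, lags_ms = seq(0, 300, by = 10)) {
  fs <- eeg$fs
  lag_samp <- lags_ms / 1000 * fs
  if (any(abs(lag_samp - round(lag_samp)) > 1e-9)) {
    abort("lags must be integer multiples of the sample period")
  }
  lag_samp <- as.integer(round(lag_samp))
  n <- ncol(eeg$data)
  n_ch <- nrow(eeg$data)
  out <- matrix(0, n, n_ch * length(lag_samp))
  for (c in seq_len(n_ch)) {
    ch <- eeg$data[c, ]
    for (l in seq_along(lag_samp)) {
      s <- lag_samp[l]
      col <- (c - 1L) * length(lag_samp) + l
      if (s < n) out[(1:(n - s)), col] <- ch[(s + 1):n]
    }
  }
  out
}

#' Train the backward envelope decoder
#'
#' Fits the ridge solution `w = (X'X + lambda I)^-1 X'y` on the lagged EEG
#' design, with predictors and target z-scored on training statistics and
#' the intercept left unpenalized (restored on output). When `lambda_grid`
#' has more than one value, lambda is chosen by contiguous-segment k-fold
#' cross-validation maximizing the mean held-out Pearson correlation. The
#' fit is deterministic given its inputs. Training data should be the
#' clear-speech (narrative) part of the session so the model reflects
#' normal speech processing rather than the experimental manipulation.
#'
#' @param training_eeg An [eeg_epoch()] at 100 Hz
#'   (see [prepare_for_decoding()]).
#' @param training_envelope An `auditory_envelope` or numeric vector,
#'   time-aligned with `training_eeg`.
#' @param lambda_grid Nonnegative ridge penalties; default log-spaced
#'   10^-6 .. 10^6.
#' @param n_folds Number of contiguous cross-validation folds.
#' @param lags_ms Decoder lags in milliseconds.
#' @return An object of class `decoder_model`: `weights` (channel x lag,
#'   original scale), `intercept`, `lags_ms`, `lambda`, `channels`, `cv`
#'   (tibble fold x lambda x r), `training_r`.
#' @export
train_decoder <- function(training_eeg, training_envelope,
                          lambda_grid = 10^seq(-6, 6, by = 1),
                          n_folds = 8, lags_ms = seq(0, 300, by = 10)) {
  y <- if (inherits(training_envelope, "auditory_envelope")) {
    training_envelope$samples
  } else {
    as.numeric(training_envelope)
  }
  n <- min(ncol(training_eeg$data), length(y))
  y <- y[seq_len(n)]
  if (ncol(training_eeg$data) > n) {
    training_eeg$data <- training_eeg$data[, seq_len(n), drop = FALSE]
  }
  if (!all(is.finite(training_eeg$data)) || !all(is.finite(y))) {
    abort("training data contain non-finite values")
  }
  if (sd(y) == 0) abort("training envelope is constant; decoder is undefined")

  X <- lag_design(training_eeg, lags_ms)
  col_mean <- colMeans(X)
  col_sd <- pmax(apply(X, 2, sd), .Machine$double.eps)
  Xz <- sweep(sweep(X, 2, col_mean), 2, col_sd, "/")
  y_mean <- mean(y)
  y_sd <- sd(y)
  yz <- (y - y_mean) / y_sd

  p <- ncol(Xz)
  solve_ridge <- function(G, b, lambda) {
    ch <- chol(G + diag(lambda, p))
    backsolve(ch, forwardsolve(t(ch), b))
  }

  cv_tbl <- NULL
  lambda <- lambda_grid[1]
  if (length(lambda_grid) > 1) {
    folds <- cut(seq_len(n), n_folds, labels = FALSE)
    G_full <- crossprod(Xz)
    b_full <- crossprod(Xz, yz)
    res <- list()
    for (f in seq_len(n_folds)) {
      idx <- which(folds == f)
      Xf <- Xz[idx, , drop = FALSE]
      G_tr <- G_full - crossprod(Xf)
      b_tr <- b_full - crossprod(Xf, yz[idx])
      for (l in lambda_grid) {
        w <- solve_ridge(G_tr, b_tr, l)
        pred <- Xf %*% w
        r <- if (sd(pred) > 0) cor(pred, yz[idx]) else 0
        res[[length(res) + 1]] <- tibble::tibble(
          fold = f, lambda = l,
          r = as.numeric(r)
        )
      }
    }
    cv_tbl <- dplyr::bind_rows(res)
    means <- dplyr::summarise(dplyr::group_by(cv_tbl, .data$lambda),
      r = mean(.data$r), .groups = "drop"
    )
    lambda <- means$lambda[which.max(means$r)]
    G <- G_full
    b <- b_full
  } else {
    G <- crossprod(Xz)
    b <- crossprod(Xz, yz)
  }

  wz <- solve_ridge(G, b, lambda)
  fit <- Xz %*% wz
  training_r <- as.numeric(cor(fit, yz))

  w_orig <- as.numeric(wz) * y_sd / col_sd
  intercept <- y_mean - sum(col_mean * w_orig)
  weights <- matrix(w_orig,
    nrow = nrow(training_eeg$data), byrow = TRUE,
    dimnames = list(training_eeg$channels, paste0("lag", lags_ms))
  )
  structure(
    list(
      weights = weights, intercept = intercept, lags_ms = lags_ms,
      lambda = lambda, channels = training_eeg$channels, fs = training_eeg$fs,
      cv = cv_tbl, training_r = training_r
    ),
    class = "decoder_model"
  )
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model> %d channels x %d lags (0-%g ms), lambda = %g, training r = %.3f\n",
    nrow(x$weights), ncol(x$weights), max(x$lags_ms), x$lambda, x$training_r
  ))
  invisible(x)
}

#' Reconstruct a stimulus envelope from EEG
#'
#' Applies a trained backward decoder to a decoder-ready epoch.
#'
#' @param model A [train_decoder()] fit.
#' @param eeg An [eeg_epoch()] at the decoder rate with matching channels.
#' @return Numeric envelope estimate, one sample per EEG sample.
#' @export
reconstruct_envelope <- function(model, eeg) {
  if (!identical(model$channels, eeg$channels)) {
    abort("EEG channels do not match the decoder's training channels")
  }
  X <- lag_design(eeg, model$lags_ms)
  as.numeric(X %*% as.numeric(t(model$weights)) + model$intercept)
}

#' Score a reconstruction against the true envelope
#'
#' Pearson correlation computed separately within each sentence-iteration
#' window (exact thirds for the standard 3 x 3.5 s stimuli). The headline
#' analysis consumes iteration 1, the first 3.5 s of a presentation.
#'
#' @param estimate Reconstructed envelope (numeric).
#' @param true_envelope `auditory_envelope` or numeric vector.
#' @param iteration_length Window length in seconds.
#' @param fs Sampling rate of both signals (Hz).
#' @return A tibble with columns `iteration` and `r`; a constant segment
#'   yields `NA` with a warning.
#' @export
score_reconstruction <- function(estimate, true_envelope,
                                 iteration_length = 3.5, fs = 100) {
  y <- if (inherits(true_envelope, "auditory_envelope")) {
    true_envelope$samples
  } else {
    as.numeric(true_envelope)
  }
  n <- min(length(estimate), length(y))
  win <- round(iteration_length * fs)
  n_iter <- max(1L, n %/% win)
  rs <- vapply(seq_len(n_iter), function(i) {
    idx <- ((i - 1) * win + 1):min(i * win, n)
    a <- estimate[idx]
    b <- y[idx]
    if (sd(a) == 0 || sd(b) == 0) {
      warn(sprintf("iteration %d is constant; correlation undefined", i))
      return(NA_real_)
    }
    cor(a, b)
  }, numeric(1))
  tibble::tibble(iteration = seq_len(n_iter), r = rs)
}

#' @rdname train_decoder
#' @param x A `decoder_model`.
#' @param ... Unused.
#' @export
tidy.decoder_model <- function(x, ...) {
  w <- x$weights
  tibble::tibble(
    channel = rep(rownames(w), times = ncol(w)),
    lag_ms = rep(x$lags_ms, each = nrow(w)),
    weight = as.numeric(w)
  )
}

#' @rdname train_decoder
#' @export
glance.decoder_model <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$weights), n_lags = ncol(x$weights),
    lambda = x$lambda, training_r = x$training_r,
    cv_r = if (is.null(x$cv)) NA_real_ else mean(x$cv$r[x$cv$lambda == x$lambda])
  )
}
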