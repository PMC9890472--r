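# autoplot() methods for the main result types (ggplot2).

#' @export
autoplot.auditory_envelope <- function(object, ...) {
  df <- tibble::tibble(
    time = (seq_along(object$samples) - 1) / object$fs,
    envelope = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$envelope)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (s)",
      y = sprintf("%g-%g Hz envelope (a.u.)", object$band[1], object$band[2]),
      title = sprintf("Auditory envelope (%s)", object$variant)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoder_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_ms, .data$channel,
    fill = .data$weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      x = "Lag (ms)", y = NULL, fill = "Weight",
      title = sprintf("Backward decoder weights (lambda = %g)", object$lambda)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
}

#' @export
autoplot.tfr <- function(object, ...) {
  pw <- apply(object$power, c(2, 3), mean)
  df <- tidyr::expand_grid(
    freq = object$freqs,
    time = object$times
  )
  df$power <- as.numeric(pw)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
    fill = log10(.data$power + 1e-20)
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "Time (s)", y = "Frequency (Hz)",
      fill = "log10 power", title = "Channel-average spectral power"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  tmap <- object$t_obs
  df <- tidyr::expand_grid(
    channel = seq_len(nrow(tmap)),
    bin = seq_len(ncol(tmap))
  )
  df$t <- tmap[cbind(df$channel, df$bin)]
  df$in_cluster <- FALSE
  for (m in object$members) {
    df$in_cluster[match(
      paste(m[, 1], m[, 2]),
      paste(df$channel, df$bin)
    )] <- TRUE
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$channel, fill = .data$t)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = ifelse(.data$in_cluster, 1, 0.4))) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(
      x = "Bin", y = "Channel", fill = "t",
      title = sprintf(
        "Cluster t map (%d cluster%s)",
        nrow(object$clusters),
        ifelse(nrow(object$clusters) == 1, "", "s")
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.induced_profile <- function(object, ...) {
  df <- tibble::tibble(
    time = object$times,
    power = colMeans(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = "log10 induced power",
      title = sprintf(
        "Induced power, %g-%g Hz (channel average)",
        object$band[1], object$band[2]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot condition cell means across participants
#'
#' One panel per measure: per-participant cell means by prior condition
#' and stimulus type, with the across-participant mean overlaid.
#'
#' @param summary A [summarize_conditions()] result.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(summary) {
  df <- summary$cell_means
  ggplot2::ggplot(df, ggplot2::aes(.data$prior, .data$value,
    color = .data$stimulus_type
  )) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3) +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(
      x = "Prior condition", y = "Cell mean",
      color = "Stimulus"
    ) +
    ggplot2::theme_minimal()
}
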