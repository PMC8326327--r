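#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accuracy / ITR curve across blink counts
#'
#' Mean subsampled accuracy (with +/- 1 SD error bars) and Wolpaw ITR as a
#' function of the number of blinks per stimulus.
#'
#' @param object A `blink_curve` from [blink_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.blink_curve <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(n_blinks = object$n_blinks, metric = "Accuracy (%)",
                   value = object$mean_accuracy,
                   lo = object$mean_accuracy - object$sd_accuracy,
                   hi = object$mean_accuracy + object$sd_accuracy),
    tibble::tibble(n_blinks = object$n_blinks, metric = "ITR (bits/min)",
                   value = object$itr_bits_min, lo = NA, hi = NA)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_blinks, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "Blinks per stimulus (N)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ERP contrast with its significance mask
#'
#' Target and nontarget mean curves with +/- 1 SE ribbons; timepoints passing
#' the false-discovery-rate mask are marked along the bottom.
#'
#' @param object An `erp_stat` from [erp_stat()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.erp_stat <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(time_ms = object$time_ms, condition = "target",
                   mean = object$mean_target, se = object$se_target),
    tibble::tibble(time_ms = object$time_ms, condition = "nontarget",
                   mean = object$mean_nontarget, se = object$se_nontarget)
  )
  sig <- object[object$significant, , drop = FALSE]
  y0 <- min(long$mean - long$se)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$mean,
                                          colour = .data$condition,
                                          fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time after flash onset (ms)", y = "Amplitude (uV)",
                  title = paste0("ERP contrast at ", attr(object, "channel"))) +
    ggplot2::theme_minimal()
  if (nrow(sig)) {
    p <- p + ggplot2::geom_point(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(x = .data$time_ms, y = y0), shape = 15, size = 1.5)
  }
  p
}

#' Plot per-channel selected-feature counts
#'
#' Bar chart of stepwise-selected feature counts per channel, front-to-back
#' ordered, with the midline channels (Fz, Cz, Pz, Oz) highlighted.
#'
#' @param counts Tibble from [channel_feature_counts()].
#' @return A ggplot object.
#' @export
plot_channel_counts <- function(counts) {
  geo <- tryCatch(channel_geometry(counts$channel), error = function(e) NULL)
  if (!is.null(geo)) {
    ord <- counts$channel[order(geo$ap, geo$lateral)]
    counts$channel <- factor(counts$channel, levels = ord)
  }
  counts$midline <- counts$channel %in% c("Fz", "Cz", "Pz", "Oz")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$channel, y = .data$n_features,
                                       fill = .data$midline)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = "Selected features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
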