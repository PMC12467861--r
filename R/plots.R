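#' Plot a confusion matrix
#'
#' Heat-map of the row-normalized confusion matrix in the canonical 13-mode
#' ordering, with per-cell percentages printed for non-zero cells.
#'
#' @param object An `lir_confusion` from [confusion_matrix()] or an `lir_eval`
#'   report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lir_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "fraction")
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = df[df$fraction > 0, ],
      ggplot2::aes(label = sprintf("%.0f", 100 * .data$fraction)), size = 2.6
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "fraction") +
    ggplot2::labs(x = "predicted mode", y = "true mode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.lir_confusion
#' @export
autoplot.lir_eval <- function(object, ...) {
  autoplot(object$confusion) +
    ggplot2::ggtitle(sprintf("%s / %s: median accuracy %.1f%% (95%% CI %.1f-%.1f%%)",
                             object$variant, object$modality,
                             100 * object$median,
                             100 * object$ci[1], 100 * object$ci[2]))
}

#' Plot an optimizer convergence history
#'
#' Best-so-far fitness per iteration of a sparrow-search run.
#'
#' @param object An `ssa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssa_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = paste0(object$variant, " convergence")) +
    ggplot2::theme_minimal()
}

#' Plot a recording
#'
#' Facetted traces of the sEMG channels (mV) and IMU axes over time, with the
#' window labels shown along the top.
#'
#' @param object An `lir_recording`.
#' @param channels Optional subset of channel names to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lir_recording <- function(object, channels = NULL, ...) {
  semg <- tibble::as_tibble(as.data.frame(object$semg))
  semg$time <- (seq_len(nrow(semg)) - 1) / object$fs_semg
  long_s <- tidyr::pivot_longer(semg, -"time",
                                names_to = "channel", values_to = "value")
  imu <- tibble::as_tibble(as.data.frame(object$imu))
  imu$time <- (seq_len(nrow(imu)) - 1) / object$fs_imu
  long_i <- tidyr::pivot_longer(imu, -"time",
                                names_to = "channel", values_to = "value")
  df <- dplyr::bind_rows(long_s, long_i)
  if (!is.null(channels)) df <- df[df$channel %in% channels, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
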