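#' ROC curve / prediction plot for a binding fit
#'
#' Classification fits draw the held-out ROC curve (with the diagonal
#' chance line); regression fits draw predicted versus observed ratios.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_fit <- function(object, ...) {
  if (object$task == "classification") {
    pos <- object$predictions$label == object$positive_class
    ord <- order(-object$predictions$prob)
    tpr <- cumsum(pos[ord]) / sum(pos)
    fpr <- cumsum(!pos[ord]) / sum(!pos)
    df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey50") +
      ggplot2::geom_path(colour = "#5e3c99", linewidth = 0.8) +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("Held-out ROC (AUC = %.2f)",
                                    object$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$predictions,
                    ggplot2::aes(x = .data$observed, y = .data$predicted)) +
      ggplot2::geom_point(alpha = 0.4, colour = "#5e3c99") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "grey30", linewidth = 0.5) +
      ggplot2::labs(x = "Observed log10 signal ratio",
                    y = "Predicted",
                    title = sprintf("Held-out prediction (r = %.2f)",
                                    object$pearson_r)) +
      ggplot2::theme_minimal()
  }
}

#' Per-position information content of a PWM
#'
#' Bar plot of column information content (bits, 0 to 2) — the summary a
#' sequence logo encodes in letter heights.
#'
#' @param x A `pwm` object.
#' @return A ggplot object.
#' @export
plot_information_content <- function(x) {
  ic <- information_content(x)
  df <- tibble::tibble(position = seq_along(ic$per_position),
                       bits = ic$per_position)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "#5e3c99") +
    ggplot2::scale_y_continuous(limits = c(0, 2)) +
    ggplot2::labs(x = "Motif position", y = "Information content (bits)",
                  title = sprintf("%s (total %.1f bits)", x$id,
                                  ic$total)) +
    ggplot2::theme_minimal()
}

#' Viewpoint interaction profile with background and called regions
#'
#' Replicate-mean normalised counts per restriction fragment against
#' genomic position, the fitted distance-decay background, and the called
#' promoter-interacting regions as shaded spans.
#'
#' @param profile A profile from [background_fit()].
#' @param pirs Optional PIR tibble from [call_pirs()].
#' @param viewpoint_pos Optional viewpoint position (vertical line).
#' @return A ggplot object.
#' @export
plot_viewpoint_profile <- function(profile, pirs = NULL,
                                   viewpoint_pos = NULL) {
  mid <- (profile$start + profile$end) / 2
  df <- tibble::tibble(pos = mid, count = profile$mean_count,
                       expected = profile$expected)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos))
  if (!is.null(pirs) && nrow(pirs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = pirs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "#fdb863", alpha = 0.4,
      inherit.aes = FALSE)
  }
  p <- p +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = 300,
                      fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       colour = "#e66101", na.rm = TRUE)
  if (!is.null(viewpoint_pos)) {
    p <- p + ggplot2::geom_vline(xintercept = viewpoint_pos,
                                 linetype = "dashed", colour = "grey30")
  }
  p + ggplot2::labs(x = "Position (bp)",
                    y = "Normalised unique interactions") +
    ggplot2::theme_minimal()
}

#' Regulation-group counts by direction
#'
#' @param summary Output of [group_summary()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  df <- summary[summary$group != "none", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "#e66101",
                                          down = "#5e3c99"),
                               na.value = "grey70") +
    ggplot2::labs(x = "Regulation group", y = "Genes",
                  fill = "Direction") +
    ggplot2::theme_minimal()
}
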