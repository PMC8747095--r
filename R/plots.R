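# ggplot2 displays of the main result types.

#' Plot median relative spectra for baseline and event windows
#'
#' Overlays the two median relative-spectrum curves (activity-free REM
#' seconds vs phasic-event windows) and marks the crossover interval when
#' found. The crossover — baseline spectra dominating below ~20 Hz, event
#' spectra above — is the empirical justification for the 20 Hz band
#' boundary of the HF:LF ratio.
#'
#' @param curve_w1,curve_w2 Tibbles from [median_spectrum()].
#' @param crossover Optional one-row tibble from [find_crossover()].
#' @return A ggplot object.
#' @export
plot_median_spectra <- function(curve_w1, curve_w2, crossover = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(curve_w1, group = "no RSWA (W1)"),
    dplyr::mutate(curve_w2, group = "RSWA window (W2)")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Median relative power",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(crossover) && isTRUE(crossover$found)) {
    p <- p + ggplot2::annotate("rect", xmin = crossover$lower_hz,
                               xmax = crossover$upper_hz, ymin = -Inf,
                               ymax = Inf, alpha = 0.2)
  }
  p
}

#' Plot the per-second HF:LF series
#'
#' @param hflf_tbl Output of [compute_hflf()].
#' @param events Optional event tibble; scored events are shaded.
#' @return A ggplot object.
#' @export
plot_hflf_series <- function(hflf_tbl, events = NULL) {
  p <- ggplot2::ggplot(hflf_tbl, ggplot2::aes(.data$second, .data$hflf)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Time (s)", y = "HF:LF") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$onset_sec,
                   xmax = .data$onset_sec + .data$duration_sec,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p
}

#' Box-violin display of HF:LF by group
#'
#' Distribution of the epoch-based (E1/E2/E3) or window-based (W1/W2)
#' values, mirroring the usual presentation of the group comparison.
#'
#' @param data A tibble such as the output of [summarize_epochs()] or
#'   [collect_window_samples()].
#' @param value Value column (tidy-eval).
#' @param group Group column (tidy-eval).
#' @return A ggplot object.
#' @export
plot_group_distributions <- function(data, value, group) {
  ggplot2::ggplot(data, ggplot2::aes({{ group }}, {{ value }})) +
    ggplot2::geom_violin(na.rm = TRUE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "HF:LF") +
    ggplot2::theme_minimal()
}

#' Pairwise mean-difference plot for an ANOVA/Tukey fit
#' @param object An `hflf_anova` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hflf_anova <- function(object, ...) {
  df <- object$pairwise
  ggplot2::ggplot(df, ggplot2::aes(
    paste(.data$group_i, "-", .data$group_j), .data$mean_diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Mean difference (Tukey 95% CI)") +
    ggplot2::theme_minimal()
}
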