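# ggplot2 visualisations: trace QC, Poincare plots, dose-response and
# incidence panels.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fluorescence trace
#'
#' @param object An [fl_trace()].
#' @param series Optional [segment_beats()] result; activation times and
#'   detected peaks are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fl_trace <- function(object, series = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$fluorescence)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("fluorescence (%s)", trace_channel(object))) +
    ggplot2::theme_minimal()
  if (!is.null(series) && nrow(series) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = series$activation_time_s,
                                 linetype = "dotted", colour = "red",
                                 alpha = 0.6)
  }
  p
}

#' Poincare plot of successive APD80s
#'
#' Mean-normalized APD80 pairs against the identity line: a tight cluster on
#' the line is a stable rhythm; scatter off it (alternans "two-cluster"
#' geometry, disorganized polygons) marks beat-to-beat instability.
#'
#' @param object A [poincare_pairs()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poincare_pairs <- function(object, ...) {
  lim <- range(c(object$prev, object$curr, 1)) + c(-0.05, 0.05)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$prev, y = .data$curr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_path(alpha = 0.35, colour = "steelblue") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_fixed(xlim = lim, ylim = lim) +
    ggplot2::labs(x = expression(APD[80]^{(n - 1)} / bar(APD)[80]),
                  y = expression(APD[80]^{(n)} / bar(APD)[80])) +
    ggplot2::theme_minimal()
}

#' Dose-response panel of a study metric
#'
#' @param report A [run_study()] report.
#' @param metric Metric column of the report's `metrics` table (default
#'   `"apd80_norm"`).
#' @return A ggplot of per-tissue values and the per-dose mean across the
#'   dose ladder (log-spaced doses shown by index).
#' @export
plot_dose_response <- function(report, metric = "apd80_norm") {
  m <- report$metrics
  if (!metric %in% names(m)) stop("no metric column ", metric, call. = FALSE)
  ggplot2::ggplot(m, ggplot2::aes(x = factor(.data$dose_um),
                                  y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey90", colour = NA, scale = "width") +
    ggplot2::geom_jitter(width = 0.08, size = 1.4, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s dose (uM)", report$design$drug),
                  y = metric) +
    ggplot2::theme_minimal()
}

#' Stacked incidence histogram across the dose ladder
#'
#' @param report A [run_study()] report.
#' @return A ggplot of per-dose arrhythmic / weak-or-silent / normal
#'   percentages.
#' @export
plot_incidence <- function(report) {
  if (is.null(report$incidence)) stop("report has no incidence table",
                                      call. = FALSE)
  ggplot2::ggplot(report$incidence,
                  ggplot2::aes(x = factor(.data$dose_index), y = .data$pct,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(arrhythmic = "firebrick",
                                          weak_or_silent = "grey20",
                                          normal = "grey80")) +
    ggplot2::labs(x = "dose index", y = "% of MPS", fill = NULL) +
    ggplot2::theme_minimal()
}
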