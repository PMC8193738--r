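#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_line
#'   geom_boxplot facet_wrap labs theme_minimal geom_hline
#' @export
ggplot2::autoplot

#' Boxplots of bulge by disc zone
#'
#' @param table a bulge tibble (from [compute_bulge()] or
#'   [normalize_bulge()]).
#' @param value column to plot (default `bulge_mm`).
#' @return A ggplot.
#' @export
plot_bulge_zones <- function(table, value = "bulge_mm") {
  table$zone <- factor(table$zone, levels = zone_names)
  ggplot(table, aes(x = .data$zone, y = .data[[value]])) +
    geom_boxplot() +
    facet_wrap(~step, labeller = ggplot2::label_both) +
    labs(x = "disc zone", y = value) +
    theme_minimal()
}

#' Load--displacement curves
#'
#' @param records tibble with `displacement_mm`, `load_N` and optionally
#'   `specimen_id`.
#' @return A ggplot.
#' @export
plot_load_curves <- function(records) {
  p <- ggplot(records, aes(x = .data$displacement_mm, y = .data$load_N))
  if ("specimen_id" %in% names(records))
    p <- p + geom_line(aes(group = .data$specimen_id,
                           colour = .data$specimen_id))
  else p <- p + geom_line()
  p + geom_point() +
    labs(x = "applied displacement (mm)", y = "peak axial load (N)") +
    theme_minimal()
}

#' @export
autoplot.agreement_result <- function(object, ...) {
  d <- tibble::tibble(invitro = object$x, insilico = object$y)
  ggplot(d, aes(x = .data$invitro, y = .data$insilico)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(title = sprintf("CCC = %.3f (%.3f, %.3f)", object$ccc,
                         object$ci95[1], object$ci95[2]),
         x = "in vitro", y = "in silico") +
    theme_minimal()
}

#' @export
autoplot.calibration_result <- function(object, ...) {
  ggplot(object$history, aes(x = .data$eval, y = .data$cost)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = 0.1 * object$max_load, linetype = 2) +
    labs(x = "forward evaluation", y = "RMS load cost (N)",
         title = "calibration convergence (dashed: 10% of max load)") +
    theme_minimal()
}
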