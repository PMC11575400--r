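#' Plot serial-transfer population trajectories
#'
#' CFU/mL per day, one line per population, log10 y axis with the
#' detection limit drawn when supplied.
#'
#' @param series Transfer-series tibble (`day`, `label`, `cfu_per_ml`,
#'   `censored`).
#' @param detection_limit Optional horizontal reference line, CFU/mL.
#' @return A ggplot object.
#' @export
plot_transfer_series <- function(series, detection_limit = NULL) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$day,
                                    y = pmax(.data$cfu_per_ml, 1),
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "day", y = "population density (CFU/mL)",
                  colour = NULL, shape = "censored") +
    ggplot2::theme_minimal()
  if (!is.null(detection_limit)) {
    p <- p + ggplot2::geom_hline(yintercept = detection_limit,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot growth curves
#'
#' OD against time, one panel-free line per well, optional log scale.
#'
#' @param plate Long tibble with `well`, `time`, `od`.
#' @param log_od Use a log10 OD axis (default FALSE).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(plate, log_od = FALSE) {
  p <- ggplot2::ggplot(plate, ggplot2::aes(x = .data$time, y = .data$od,
                                           group = .data$well,
                                           colour = .data$well)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (h)", y = "OD", colour = "well") +
    ggplot2::theme_minimal()
  if (log_od) p <- p + ggplot2::scale_y_log10()
  p
}

#' Histogram of a trait sample with the dip-test annotation
#'
#' @param values Numeric trait values.
#' @param trait_name Axis label.
#' @param bins Histogram bins (default 20).
#' @return A ggplot object.
#' @export
plot_trait_distribution <- function(values, trait_name = "trait", bins = 20) {
  ggplot2::ggplot(tibble::tibble(value = values),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::labs(x = trait_name, y = "clones") +
    ggplot2::theme_minimal()
}

#' Plot the Monod fit over its (R, q) cloud
#'
#' @param fit A `monod_fit` object.
#' @return A ggplot object.
#' @export
autoplot.monod_fit <- function(fit, ...) {
  pts <- if (!is.null(fit$fit)) {
    tibble::tibble(R = fit$fit$m$getEnv()$R, q = fit$fit$m$getEnv()$q)
  } else {
    tibble::tibble(R = numeric(0), q = numeric(0))
  }
  grid <- tibble::tibble(R = seq(0, max(c(pts$R, fit$K * 10, 0.1)),
                                 length.out = 200))
  grid$q <- fit$V * grid$R / (fit$K + grid$R)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$R, y = .data$q)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "resource (mM)", y = "uptake rate q (mM/OD/h)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
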