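# ggplot2 displays for the main result types.

#' Plot a fitted extended Cushing model with its prediction band
#'
#' Observed hatchling counts per year with the fitted median and a
#' prediction band under the exact (positively skewed) response
#' distribution.
#'
#' @param object An `extended_cushing_fit`.
#' @param levels Band quantile levels, default `c(0.025, 0.975)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot extended_cushing_fit
#' @export
autoplot.extended_cushing_fit <- function(object, levels = c(0.025, 0.975), ...) {
  band <- prediction_band(object, levels = levels)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.6) +
    ggplot2::geom_point(data = object$data, ggplot2::aes(y = .data$R)) +
    ggplot2::labs(x = "Year", y = "Hatchlings (R)",
                  title = "Extended Cushing fit",
                  subtitle = sprintf("%.0f%% prediction band", 100 * diff(levels))) +
    ggplot2::theme_minimal()
}

#' Plot a windowed shape-exponent series against a climate cycle
#'
#' Time series of the locally estimated Cushing exponent `b` (one point per
#' window right endpoint), optionally overlaid with a lagged harmonic cycle
#' rescaled to the range of `b` for visual comparison.
#'
#' @param local_fits Tibble from [local_cushing()].
#' @param cycle Optional `harmonic_cycle` to overlay.
#' @param lag Lag (years) applied to the overlaid cycle.
#' @return A ggplot object.
#' @export
plot_local_b <- function(local_fits, cycle = NULL, lag = 0) {
  p <- ggplot2::ggplot(local_fits, ggplot2::aes(x = .data$year, y = .data$b)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Window right endpoint", y = "Shape exponent b",
                  title = "Windowed Cushing exponent") +
    ggplot2::theme_minimal()
  if (!is.null(cycle)) {
    cyc <- eval_cycle(cycle, local_fits$year, lag = lag)
    rng_b <- range(local_fits$b)
    rng_T <- range(cyc$T)
    if (diff(rng_T) > 0) {
      cyc$scaled <- rng_b[1] + (cyc$T - rng_T[1]) / diff(rng_T) * diff(rng_b)
      p <- p + ggplot2::geom_line(data = cyc,
                                  ggplot2::aes(y = .data$scaled),
                                  linetype = "dashed", colour = "steelblue")
    }
  }
  p
}

#' Plot a lag scan
#'
#' Squared correlation against lag, with the selected lag highlighted.
#'
#' @param object A `lag_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lag_scan
#' @export
autoplot.lag_scan <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lag, y = .data$r2)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$best), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "Lag (years)", y = expression(r^2),
                  title = "Lagged correlation with cycle") +
    ggplot2::theme_minimal()
}
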