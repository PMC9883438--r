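# Fixed-period harmonic extraction from an annual climate index, analytic
# evaluation of the fitted cycle at (lagged) years, and a lag scan that finds
# the lag maximizing squared correlation with a target annual series.

#' Construct a fixed-period harmonic cycle
#'
#' The cycle is the sinusoid
#' `offset + amplitude * sin(2*pi*(t - phase)/period)`, defined for every
#' year `t`, so evaluation is never truncated by the span of the index it was
#' extracted from.
#'
#' @param period Period in years (> 0). The analysis default is the 26-year
#'   multidecadal SST cycle.
#' @param amplitude Amplitude in index units (>= 0).
#' @param phase Phase in years; stored modulo `period`.
#' @param offset Vertical offset (mean level) in index units.
#' @return An object of class `harmonic_cycle`.
#' @examples
#' harmonic_cycle(period = 26, amplitude = 0.2, phase = 5, offset = 0)
#' @export
harmonic_cycle <- function(period = 26, amplitude, phase, offset = 0) {
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) || period <= 0) {
    stop_param("`period` must be a single positive number of years.")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1 || !is.finite(amplitude) ||
      amplitude < 0) {
    stop_param("`amplitude` must be a single non-negative number.")
  }
  if (!is.numeric(phase) || length(phase) != 1 || !is.finite(phase)) {
    stop_param("`phase` must be a single finite number of years.")
  }
  if (!is.numeric(offset) || length(offset) != 1 || !is.finite(offset)) {
    stop_param("`offset` must be a single finite number.")
  }
  structure(
    list(period = period, amplitude = amplitude,
         phase = phase %% period, offset = offset),
    class = "harmonic_cycle"
  )
}

#' @export
print.harmonic_cycle <- function(x, ...) {
  cat(sprintf("Harmonic cycle: period %.4g yr, amplitude %.4g, phase %.4g yr, offset %.4g\n",
              x$period, x$amplitude, x$phase, x$offset))
  if (!is.null(x$r2)) cat(sprintf("  extraction fit: r2 = %.4f on n = %d years\n", x$r2, x$n))
  invisible(x)
}

#' Extract a fixed-period harmonic from a climate index
#'
#' Least-squares fit of a single sinusoid of known period to an annual index:
#' `value_t ~ offset + amplitude * sin(2*pi*(t - phase)/period)` with the
#' period held fixed. The fit is linear in the equivalent sin/cos
#' parameterization `offset + c_s*sin(w*t) + c_c*cos(w*t)`, from which
#' `amplitude = sqrt(c_s^2 + c_c^2)` and the phase follow.
#'
#' @param index Climate-index tibble with columns `year`, `value`, e.g. from
#'   [read_climate_index()].
#' @param period Fixed period in years (default 26).
#' @param span Optional length-2 year range restricting the fit (e.g.
#'   `c(1900, 2010)`); the fitted cycle still evaluates at any year.
#' @return A `harmonic_cycle` with extra fields `r2` (variance explained) and
#'   `n` (years used).
#' @examples
#' idx <- tibble::tibble(year = 1900:2010,
#'                       value = sin(2 * pi * (1900:2010 - 5) / 26))
#' fit_harmonic(idx, period = 26)
#' @export
fit_harmonic <- function(index, period = 26, span = NULL) {
  if (!is.data.frame(index) || !all(c("year", "value") %in% names(index))) {
    stop_schema("`index` must have columns year, value.")
  }
  index <- tibble::as_tibble(index)
  if (!is.null(span)) {
    index <- dplyr::filter(index, .data$year >= span[1], .data$year <= span[2])
  }
  if (nrow(index) < 4) {
    stop_data("harmonic extraction needs at least 4 index points.")
  }
  if (sd(index$value) == 0) {
    warn("climate index has zero variance; returning amplitude 0.")
    out <- harmonic_cycle(period, 0, 0, index$value[1])
    out$r2 <- NA_real_
    out$n <- nrow(index)
    return(out)
  }
  w <- 2 * pi / period
  s <- sin(w * index$year)
  c_ <- cos(w * index$year)
  fit <- lm(index$value ~ s + c_)
  cf <- coef(fit)
  c_s <- unname(cf["s"])
  c_c <- unname(cf["c_"])
  # c_s*sin(wt) + c_c*cos(wt) = A*sin(w*(t - phase)) with
  # c_s = A*cos(w*phase), c_c = -A*sin(w*phase)
  amplitude <- sqrt(c_s^2 + c_c^2)
  phase <- if (amplitude == 0) 0 else atan2(-c_c, c_s) / w
  out <- harmonic_cycle(period, amplitude, phase, unname(cf[1]))
  out$r2 <- summary(fit)$r.squared
  out$n <- nrow(index)
  out
}

#' Evaluate a harmonic cycle at given years, with a lag
#'
#' Produces the cycle covariate series `T_t = cycle(t - lag)`: the covariate
#' looks back `lag` years. The sinusoid is analytic, so evaluation outside
#' the span the cycle was extracted from never truncates the paired
#' abundance series. A lag equal to the period reproduces lag 0.
#'
#' @param cycle A `harmonic_cycle`.
#' @param years Integer vector of calendar years at which to evaluate.
#' @param lag Non-negative integer lag in years (default 0).
#' @return A tibble with columns `year`, `T`.
#' @examples
#' cyc <- harmonic_cycle(26, 0.2, 22.5, 0)
#' eval_cycle(cyc, 1984:2020, lag = 3)
#' @export
eval_cycle <- function(cycle, years, lag = 0) {
  if (!inherits(cycle, "harmonic_cycle")) stop_param("`cycle` must be a harmonic_cycle.")
  if (!is.numeric(lag) || length(lag) != 1 || !is_whole(lag) || lag < 0) {
    stop_param("`lag` must be a non-negative whole number of years.")
  }
  if (!is.numeric(years) || length(years) == 0) stop_param("`years` must be numeric.")
  t_eff <- years - lag
  T_val <- cycle$offset +
    cycle$amplitude * sin(2 * pi * (t_eff - cycle$phase) / cycle$period)
  tibble::tibble(year = years, T = T_val)
}

#' Scan lags for maximal squared correlation with a target series
#'
#' For each lag in `0..max_lag`, computes the Pearson correlation between the
#' target series at year `t` and the cycle evaluated at `t - lag`, then
#' selects the lag with the largest squared correlation (so a strong inverse
#' relationship is found just as readily as a direct one). Ties are broken
#' toward the smallest lag.
#'
#' @param target A data frame whose first column is `year` and whose second
#'   column is the annual value to correlate (for example the windowed shape
#'   exponent `b` from [local_cushing()], passed as `(year, b)`).
#' @param cycle A `harmonic_cycle`.
#' @param max_lag Largest lag (years) to try; must satisfy
#'   `0 <= max_lag < nrow(target) - 2`.
#' @return An object of class `lag_scan`: list with `table` (tibble `lag`,
#'   `r`, `r2`) and `best_lag`. Has a [tidy()] method.
#' @examples
#' cyc <- harmonic_cycle(26, 1, 5, 0)
#' target <- eval_cycle(cyc, 1992:2020, lag = 3)
#' names(target) <- c("year", "b")
#' lag_scan(target, cyc, max_lag = 8)$best_lag  # 3
#' @export
lag_scan <- function(target, cycle, max_lag) {
  if (!is.data.frame(target) || ncol(target) < 2) {
    stop_schema("`target` must be a data frame with year in column 1 and values in column 2.")
  }
  if (!inherits(cycle, "harmonic_cycle")) stop_param("`cycle` must be a harmonic_cycle.")
  years <- target[[1]]
  values <- target[[2]]
  n <- length(values)
  if (n < 3) stop_data("lag scan needs a target series of at least 3 years.")
  if (!is.numeric(max_lag) || length(max_lag) != 1 || !is_whole(max_lag) ||
      max_lag < 0 || max_lag >= n - 2) {
    stop_param("`max_lag` must satisfy 0 <= max_lag < length(target) - 2.")
  }
  if (sd(values) == 0) {
    stop_data("target series is constant: correlation with the cycle is undefined.")
  }
  tab <- purrr::map_dfr(0:max_lag, function(l) {
    T_l <- eval_cycle(cycle, years, lag = l)$T
    r <- if (sd(T_l) == 0) NA_real_ else cor(values, T_l)
    tibble::tibble(lag = l, r = r, r2 = r^2)
  })
  best <- tab$lag[which.max(tab$r2)]  # which.max takes the first (smallest lag) on ties
  structure(list(table = tab, best_lag = best), class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("Lag scan over 0..%d years; best lag = %d (r = %.3f, r2 = %.3f)\n",
              max(x$table$lag), x$best_lag,
              x$table$r[x$table$lag == x$best_lag],
              x$table$r2[x$table$lag == x$best_lag]))
  invisible(x)
}

#' Tidy a lag scan
#'
#' @param x A `lag_scan`.
#' @param ... Unused.
#' @return The per-lag tibble with columns `lag`, `r`, `r2`, `best` (logical).
#' @method tidy lag_scan
#' @export
tidy.lag_scan <- function(x, ...) {
  dplyr::mutate(x$table, best = .data$lag == x$best_lag)
}
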