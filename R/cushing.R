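# Static Cushing stock-recruitment model R = a * S^b and its linearized
# ln-ln OLS fit, plus the sliding-window local regression used to track
# drift in the shape exponent b over time.

#' Median recruitment under the Cushing power-law model
#'
#' Evaluates `R = a * S^b`, the Cushing stock-recruitment curve: recruitment
#' grows without a plateau as stock grows, accelerating for `b > 1`, linear at
#' `b = 1`, decelerating for `b < 1`.
#'
#' @param S Nesting-female (stock) abundance, strictly positive. Vectorized.
#' @param a Conversion factor, `a > 0` (units of hatchlings per nester^`b`).
#' @param b Dimensionless shape exponent.
#' @return Expected (median) hatchling numbers, same length as `S`.
#' @examples
#' cushing_median(1, a = 2, b = 1.7)   # S = 1 returns a
#' cushing_median(10, a = 1, b = 2)    # 100
#' @export
cushing_median <- function(S, a, b) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    stop_param("`a` must be a single positive number.")
  }
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b)) {
    stop_param("`b` must be a single finite number.")
  }
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0)) {
    stop_domain("`S` must be strictly positive.")
  }
  a * S^b
}

#' Fit the Cushing model by linearized least squares
#'
#' The power law linearizes as `ln(R) = ln(a) + b * ln(S)`; the fit is
#' ordinary least squares of `ln(R)` on `ln(S)`, with `a = exp(intercept)`
#' and `b = slope`. `r2` is the squared Pearson correlation of the ln-ln
#' regression.
#'
#' @param data Abundance tibble with columns `year`, `S`, `R` (all positive,
#'   at least 2 rows).
#' @return An object of class `cushing_fit`: a list with elements `a`, `b`,
#'   `r2`, `sigma_ln` (residual sd on the ln scale, `NA` with 0 residual df),
#'   `n` and `window` (first and last year fitted). Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' d <- tibble::tibble(year = 1:9, S = seq(10, 90, 10), R = 2 * seq(10, 90, 10)^1.5)
#' fit_cushing(d)
#' @export
fit_cushing <- function(data) {
  data <- validate_abundance(data)
  if (sd(log(data$S)) == 0) {
    stop_data("all S values are identical: the ln-ln design is singular.")
  }
  ln_S <- log(data$S)
  ln_R <- log(data$R)
  fit <- lm(ln_R ~ ln_S)
  # r2 and residual sd computed directly (summary.lm warns on exact fits)
  rss <- sum(fit$residuals^2)
  tss <- sum((ln_R - mean(ln_R))^2)
  structure(
    list(
      a = exp(unname(coef(fit)[1])),
      b = unname(coef(fit)[2]),
      r2 = if (tss > 0) 1 - rss / tss else NA_real_,
      sigma_ln = if (fit$df.residual > 0) sqrt(rss / fit$df.residual) else NA_real_,
      n = nrow(data),
      window = c(start = min(data$year), end = max(data$year))
    ),
    class = "cushing_fit"
  )
}

#' @export
print.cushing_fit <- function(x, ...) {
  cat(sprintf("Cushing fit ln(R) = ln(a) + b ln(S), years %d-%d (n = %d)\n",
              x$window[["start"]], x$window[["end"]], x$n))
  cat(sprintf("  a = %.4g, b = %.4f, r2 = %.4f\n", x$a, x$b, x$r2))
  invisible(x)
}

#' @export
coef.cushing_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Tidy a Cushing fit
#'
#' @param x A `cushing_fit`.
#' @param ... Unused.
#' @return A one-row-per-parameter tibble with columns `term`, `estimate`.
#' @method tidy cushing_fit
#' @export
tidy.cushing_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' Glance at a Cushing fit
#'
#' @param x A `cushing_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma_ln`, `nobs`,
#'   `year_start`, `year_end`.
#' @method glance cushing_fit
#' @export
glance.cushing_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma_ln = x$sigma_ln, nobs = x$n,
                 year_start = x$window[["start"]], year_end = x$window[["end"]])
}

#' Sliding-window local regression of the Cushing model
#'
#' Refits the linearized Cushing model on successive windows of `window`
#' consecutive years, assigning each estimate to the window's right endpoint.
#' A series of `n` consecutive years yields exactly `n - window + 1` rows;
#' e.g. a 37-year series with the default 9-year window yields 29 estimates,
#' the first keyed to the 9th year. Tracking the windowed shape exponent `b`
#' over time reveals drift in the recruitment regime.
#'
#' @param data Abundance tibble with columns `year`, `S`, `R`; years must be
#'   consecutive (no gaps) and at least `window` long.
#' @param window Window length in years (default 9). Must be at least 2.
#' @return A tibble with one row per window: `year` (right endpoint),
#'   `start_year`, `end_year`, `n`, `a`, `b`, `r2`.
#' @examples
#' d <- tibble::tibble(year = 1984:2020, S = round(6 * exp(0.17 * 0:36)))
#' d$R <- round(250 * d$S^1.05)
#' local_cushing(d, window = 9)
#' @export
local_cushing <- function(data, window = 9) {
  if (!is.numeric(window) || length(window) != 1 || !is_whole(window) || window < 2) {
    stop_param("`window` must be a whole number >= 2.")
  }
  data <- validate_abundance(data, require_consecutive = TRUE)
  n <- nrow(data)
  if (n < window) {
    stop_data(sprintf("series has %d years but the window needs %d.", n, window))
  }
  purrr::map_dfr(seq_len(n - window + 1), function(i) {
    fit <- fit_cushing(data[i:(i + window - 1), ])
    tibble::tibble(
      year = fit$window[["end"]],
      start_year = fit$window[["start"]],
      end_year = fit$window[["end"]],
      n = fit$n,
      a = fit$a,
      b = fit$b,
      r2 = fit$r2
    )
  })
}
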