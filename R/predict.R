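# Prediction intervals under the exact response distribution of the extended
# Cushing model, and residual diagnostics for a fitted model.

# CDF of R = (mu + s*eps)^2 with eps ~ N(0,1), s = sigma/2:
#   P(R <= r) = Phi((sqrt(r) - mu)/s) - Phi((-sqrt(r) - mu)/s)
# (both branches of the square contribute). Monotone in r.
ec_cdf <- function(r, mu, s) {
  x <- sqrt(pmax(r, 0))
  pnorm((x - mu) / s) - pnorm((-x - mu) / s)
}

# Quantile by monotone root-finding on the sqrt scale. When mu/s is large the
# folded branch is numerically zero and the closed form (mu + s*z)^2 is
# identical; it is used only in that regime.
ec_quantile <- function(level, mu, s) {
  if (s == 0) return(mu^2)
  z <- qnorm(level)
  if (mu / s > 8) return((pmax(mu + s * z, 0))^2)
  f <- function(x) pnorm((x - mu) / s) - pnorm((-x - mu) / s) - level
  hi <- max(mu + s * (abs(z) + 2), mu + 10 * s, s)
  while (f(hi) < 0) hi <- hi * 2
  root <- uniroot(f, lower = 0, upper = hi, tol = .Machine$double.eps^0.75)
  root$root^2
}

#' Prediction band for the extended Cushing model
#'
#' For each year, computes the median (the Cushing curve `a*S^b(T)`) and the
#' requested quantiles of the response distribution
#' `R = (sqrt(a*S^b(T)) + (sigma/2)*eps)^2`. Quantiles are exact: they invert
#' the two-sided CDF of the squared shifted normal by monotone root-finding,
#' which remains valid when the median is small relative to the noise. The
#' distribution is positively skewed, so the band is asymmetric about the
#' median and widens as the median grows.
#'
#' @param params An `extended_params` object or a fitted
#'   `extended_cushing_fit` (whose estimates and data are then used).
#' @param newdata Data frame with columns `year`, `S`, `T` at which to
#'   evaluate the band. Defaults to the fitted data when `params` is a fit.
#' @param levels Two quantile levels in (0, 1), default `c(0.025, 0.975)`
#'   (a 95% prediction interval).
#' @return A tibble with columns `year`, `S`, `T`, `median`, `lower`,
#'   `upper`.
#' @examples
#' p <- extended_params(264.299, 0.999, -0.615, 50.65)
#' nd <- tibble::tibble(year = 2000:2002, S = c(100, 120, 150), T = c(0.1, 0.15, 0.2))
#' prediction_band(p, nd)
#' @export
prediction_band <- function(params, newdata = NULL, levels = c(0.025, 0.975)) {
  if (is.null(newdata)) {
    if (!inherits(params, "extended_cushing_fit")) {
      stop_param("`newdata` is required unless `params` is a fitted model.")
    }
    newdata <- params$data
  }
  pars <- as_extended_params(params)
  if (!is.data.frame(newdata) || !all(c("year", "S", "T") %in% names(newdata))) {
    stop_schema("`newdata` must have columns year, S, T.")
  }
  if (!is.numeric(levels) || length(levels) != 2 ||
      any(levels <= 0) || any(levels >= 1)) {
    stop_param("`levels` must be two probabilities strictly inside (0, 1).")
  }
  levels <- sort(levels)
  med <- median_response(pars, newdata$S, newdata$T)
  mu <- sqrt(med)
  s <- pars$sigma / 2
  tibble::tibble(
    year = newdata$year,
    S = newdata$S,
    T = newdata$T,
    median = med,
    lower = purrr::map_dbl(mu, ~ ec_quantile(levels[1], .x, s)),
    upper = purrr::map_dbl(mu, ~ ec_quantile(levels[2], .x, s))
  )
}

#' Residual diagnostics for an extended Cushing fit
#'
#' Tests the two distributional assumptions of the noise model on the
#' standardized square-root-scale residuals: normality (Shapiro-Wilk) and
#' serial independence (Ljung-Box at lag `min(10, floor(n/5))`).
#'
#' @param fit An `extended_cushing_fit` with at least 8 residuals.
#' @param alpha Significance level for the pass flags (default 0.05).
#' @return An object of class `diagnostics_report`: tibble with one row per
#'   test (`test`, `statistic`, `p.value`, `pass`).
#' @export
diagnostics <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "extended_cushing_fit")) {
    stop_param("`fit` must be an extended_cushing_fit.")
  }
  e <- fit$residuals
  n <- length(e)
  if (n < 8) stop_data("diagnostics need at least 8 residuals.")
  sw <- shapiro.test(e)
  lb_lag <- min(10, floor(n / 5))
  lb <- Box.test(e, lag = lb_lag, type = "Ljung-Box")
  out <- tibble::tibble(
    test = c("normality (Shapiro-Wilk)",
             sprintf("independence (Ljung-Box, lag %d)", lb_lag)),
    statistic = c(unname(sw$statistic), unname(lb$statistic)),
    p.value = c(sw$p.value, lb$p.value),
    pass = c(sw$p.value > alpha, lb$p.value > alpha)
  )
  class(out) <- c("diagnostics_report", class(out))
  attr(out, "alpha") <- alpha
  out
}
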