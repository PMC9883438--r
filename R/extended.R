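# The extended Cushing model: the shape exponent b becomes a linear function
# of a climate covariate T, b(T) = gamma0 + gamma1*T, and the response is
# perturbed on the square-root scale,
#   R = (sqrt(a * S^b(T)) + (sigma/2) * eps)^2,   eps ~ N(0, 1) iid,
# which induces positive skew and variance growing with the median. With
# sigma = 0 (or gamma1 = 0) the static Cushing relationship is recovered
# exactly, so the classical model is embedded.

#' Construct extended-Cushing parameters
#'
#' @param a Conversion factor, `a > 0`.
#' @param gamma0 Baseline shape exponent (the value of `b` at `T = 0`).
#' @param gamma1 Sensitivity of the exponent to the climate covariate
#'   (per anomaly unit); `gamma1 = 0` means no climate effect.
#' @param sigma Noise scale, `sigma >= 0`; `sqrt(R)` has standard deviation
#'   `sigma/2` around `sqrt(a*S^b)`. `sigma = 0` gives the deterministic
#'   Cushing curve.
#' @return An object of class `extended_params`.
#' @examples
#' extended_params(a = 264.299, gamma0 = 0.999, gamma1 = -0.615, sigma = 50.65)
#' @export
extended_params <- function(a, gamma0, gamma1, sigma) {
  for (nm in c("a", "gamma0", "gamma1", "sigma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop_param(paste0("`", nm, "` must be a single finite number."))
    }
  }
  if (a <= 0) stop_param("`a` must be positive.")
  if (sigma < 0) stop_param("`sigma` must be non-negative.")
  structure(list(a = a, gamma0 = gamma0, gamma1 = gamma1, sigma = sigma),
            class = "extended_params")
}

#' @export
print.extended_params <- function(x, ...) {
  cat(sprintf("Extended Cushing parameters: a = %.4g, gamma0 = %.4g, gamma1 = %.4g, sigma = %.4g\n",
              x$a, x$gamma0, x$gamma1, x$sigma))
  invisible(x)
}

as_extended_params <- function(x) {
  if (inherits(x, "extended_params")) return(x)
  if (inherits(x, "extended_cushing_fit")) return(x$params)
  stop_param("expected an `extended_params` object or an extended-Cushing fit.")
}

#' Shape exponent as a function of the climate covariate
#'
#' Evaluates `b(T) = gamma0 + gamma1 * T`.
#'
#' @param params An `extended_params` object (or fitted model).
#' @param T Climate covariate value(s), anomaly units. Vectorized.
#' @return The exponent `b` at each `T`.
#' @examples
#' p <- extended_params(264.299, 0.999, -0.615, 50.65)
#' shape_exponent(p, T = 0)    # gamma0
#' shape_exponent(p, T = 1)    # 0.384
#' @export
shape_exponent <- function(params, T) {
  params <- as_extended_params(params)
  if (!is.numeric(T) || any(!is.finite(T))) stop_param("`T` must be finite.")
  params$gamma0 + params$gamma1 * T
}

#' Median recruitment under the extended Cushing model
#'
#' Evaluates `med(R) = a * S^(gamma0 + gamma1*T)`. This is the median (not
#' the mean) of the skewed response distribution, and does not depend on
#' `sigma`. With `gamma1 = 0` it reduces to [cushing_median()] for every `T`.
#'
#' @inheritParams shape_exponent
#' @param S Nesting-female abundance, strictly positive. Vectorized; `S` and
#'   `T` are recycled to a common length.
#' @return Median hatchling numbers.
#' @export
median_response <- function(params, S, T) {
  params <- as_extended_params(params)
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0)) {
    stop_domain("`S` must be strictly positive.")
  }
  b <- shape_exponent(params, T)
  params$a * S^b
}

#' Recruitment rate: hatchlings per additional nester
#'
#' The derivative of the median response with respect to stock,
#' `RR = a * (gamma0 + gamma1*T) * S^(gamma0 + gamma1*T - 1)`: the marginal
#' number of hatchlings produced per unit increase in nesting females at
#' stock level `S` under climate state `T`.
#'
#' @inheritParams median_response
#' @return Recruitment rate at each `(S, T)`.
#' @export
recruitment_rate <- function(params, S, T) {
  params <- as_extended_params(params)
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0)) {
    stop_domain("`S` must be strictly positive.")
  }
  b <- shape_exponent(params, T)
  params$a * b * S^(b - 1)
}

#' Simulate hatchling counts from the extended Cushing model
#'
#' Draws `R = (sqrt(a*S^b(T)) + (sigma/2)*eps)^2` with independent standard
#' normal `eps`, one draw per `(S, T)` pair. With `sigma = 0` the draw equals
#' [median_response()] exactly.
#'
#' @inheritParams median_response
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Non-negative simulated hatchling numbers (not rounded).
#' @examples
#' p <- extended_params(264.299, 0.999, -0.615, 50.65)
#' simulate_response(p, S = c(10, 100), T = c(0.1, -0.1), seed = 1)
#' @export
simulate_response <- function(params, S, T, seed = NULL) {
  params <- as_extended_params(params)
  med <- median_response(params, S, T)
  if (params$sigma == 0) return(med)   # exact degeneracy, no sqrt round-trip
  mu <- sqrt(med)
  n <- length(mu)
  draw <- function() (mu + (params$sigma / 2) * rnorm(n))^2
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Sum of squares on the sqrt scale and its analytic gradient in
# th = (log a, gamma0, gamma1). mu = sqrt(a) * S^(b/2).
ec_rss <- function(th, sqrtR, logS, T) {
  mu <- exp(0.5 * (th[1] + (th[2] + th[3] * T) * logS))
  sum((sqrtR - mu)^2)
}

ec_rss_grad <- function(th, sqrtR, logS, T) {
  mu <- exp(0.5 * (th[1] + (th[2] + th[3] * T) * logS))
  e <- sqrtR - mu
  -2 * c(sum(e * mu) / 2,
         sum(e * mu * logS) / 2,
         sum(e * mu * T * logS) / 2)
}

#' Fit the extended Cushing model by maximum likelihood
#'
#' Under the model, `sqrt(R_t)` is Normal with mean `sqrt(a*S_t^(gamma0 +
#' gamma1*T_t))` and standard deviation `sigma/2`, so maximum likelihood for
#' the mean parameters is nonlinear least squares on the square-root scale.
#' `a` is parameterized internally on the log scale to enforce positivity,
#' the optimizer (BFGS with analytic gradient) is started from the linearized
#' whole-series Cushing fit with `gamma1 = 0`, and `sigma` is profiled from
#' the residuals. Wald standard errors come from the Jacobian of the mean
#' function at the optimum; 95% confidence limits are `estimate +/- 1.96*SE`
#' and p-values are two-sided t with `n - p` degrees of freedom (`p` mean
#' parameters).
#'
#' @param data Abundance tibble with columns `year`, `S`, `R` (`n >= 5`).
#' @param cycle_data Cycle covariate tibble with columns `year`, `T` covering
#'   exactly the same years (e.g. from [eval_cycle()] with the chosen lag).
#' @param gamma1 `NULL` (default) to estimate the climate sensitivity, or a
#'   fixed numeric value (typically 0) to hold it constant. When the supplied
#'   `T` is constant, `gamma1` is unidentifiable and the fit refuses unless
#'   it is fixed.
#' @param sigma How to scale the noise estimate from the residual sum of
#'   squares: `"least-squares"` (default) uses `2*sqrt(RSS/(n - p))`, the
#'   residual-standard-error convention of nonlinear least squares; `"ml"`
#'   uses the pure maximum-likelihood `2*sqrt(RSS/n)`.
#' @return An object of class `extended_cushing_fit` with elements `params`
#'   (an [extended_params()] holding the estimates), `coefficients` (tibble:
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`, `statistic`,
#'   `p.value`), `sigma`, `loglik` (sqrt-scale Gaussian log-likelihood at the
#'   profile-ML sigma), `residuals` (standardized sqrt-scale), `fitted`
#'   (medians per year), `data` (the joined year/S/R/T table), `df.residual`,
#'   `rss`. Has [tidy()], [glance()], [augment()] and [autoplot()] methods.
#' @examples
#' cfg <- synth_config(seed = 42)
#' d <- generate_dataset(cfg)
#' fit_extended(d$abundance, d$cycle)
#' @export
fit_extended <- function(data, cycle_data, gamma1 = NULL,
                         sigma = c("least-squares", "ml")) {
  sigma <- match.arg(sigma)
  data <- validate_abundance(data)
  if (!is.data.frame(cycle_data) || !all(c("year", "T") %in% names(cycle_data))) {
    stop_schema("`cycle_data` must have columns year, T.")
  }
  if (!setequal(data$year, cycle_data$year)) {
    stop_data("abundance and cycle series must cover identical years.")
  }
  d <- dplyr::inner_join(data, tibble::as_tibble(cycle_data)[c("year", "T")],
                         by = "year")
  n <- nrow(d)
  if (n < 5) stop_data("extended-model fit needs at least 5 years.")
  fix_g1 <- !is.null(gamma1)
  if (fix_g1 && (!is.numeric(gamma1) || length(gamma1) != 1 || !is.finite(gamma1))) {
    stop_param("fixed `gamma1` must be a single finite number.")
  }
  if (!fix_g1 && sd(d$T) == 0) {
    stop_data(paste("the climate covariate T is constant, so gamma1 is not",
                    "identifiable; refit with gamma1 fixed (gamma1 = 0)."))
  }
  sqrtR <- sqrt(d$R)
  logS <- log(d$S)

  init_lm <- fit_cushing(d)
  th0 <- c(log(init_lm$a), init_lm$b, if (fix_g1) NULL else 0)

  if (fix_g1) {
    obj <- function(th) ec_rss(c(th, gamma1), sqrtR, logS, d$T)
    grd <- function(th) ec_rss_grad(c(th, gamma1), sqrtR, logS, d$T)[1:2]
  } else {
    obj <- function(th) ec_rss(th, sqrtR, logS, d$T)
    grd <- function(th) ec_rss_grad(th, sqrtR, logS, d$T)
  }
  opt <- optim(th0, obj, grd, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  converged <- opt$convergence == 0
  # polish with Nelder-Mead; near-degenerate simplexes (code 10) at the
  # optimum are harmless once BFGS has converged
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  converged <- converged || opt2$convergence == 0
  if (opt2$value < opt$value) opt <- opt2
  if (!converged) {
    stop_data(paste0("extended-model optimizer failed to converge (code ",
                     opt$convergence, "; RSS = ", signif(opt$value, 6), ")."))
  }

  a_hat <- exp(opt$par[1])
  g0_hat <- opt$par[2]
  g1_hat <- if (fix_g1) gamma1 else opt$par[3]
  b_hat <- g0_hat + g1_hat * d$T
  mu <- sqrt(a_hat) * d$S^(b_hat / 2)
  e <- sqrtR - mu
  rss <- sum(e^2)
  p <- if (fix_g1) 2L else 3L
  df_res <- n - p
  s2 <- rss / df_res
  sigma_hat <- if (sigma == "ml") 2 * sqrt(rss / n) else 2 * sqrt(s2)

  # Jacobian of mu in the natural parameters (a, gamma0[, gamma1])
  J <- cbind(mu / (2 * a_hat), mu * logS / 2,
             if (fix_g1) NULL else mu * d$T * logS / 2)
  vcov_mat <- s2 * solve(crossprod(J))
  se <- sqrt(diag(vcov_mat))
  est <- c(a_hat, g0_hat, if (fix_g1) NULL else g1_hat)
  terms <- c("a", "gamma0", if (fix_g1) NULL else "gamma1")
  dimnames(vcov_mat) <- list(terms, terms)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = df_res)
  coefs <- tibble::tibble(
    term = terms, estimate = est, std.error = se,
    conf.low = est - 1.96 * se, conf.high = est + 1.96 * se,
    statistic = tval, p.value = pval
  )

  sigma_ml <- 2 * sqrt(rss / n)
  loglik <- if (rss > 0) sum(dnorm(sqrtR, mu, sigma_ml / 2, log = TRUE)) else Inf

  structure(
    list(
      params = extended_params(a_hat, g0_hat, g1_hat, sigma_hat),
      coefficients = coefs,
      sigma = sigma_hat,
      sigma_method = sigma,
      gamma1_fixed = fix_g1,
      loglik = loglik,
      rss = rss,
      df.residual = df_res,
      vcov = vcov_mat,
      fitted = a_hat * d$S^b_hat,
      residuals = if (sigma_hat > 0) e / (sigma_hat / 2) else e,
      data = d
    ),
    class = "extended_cushing_fit"
  )
}

#' @export
print.extended_cushing_fit <- function(x, ...) {
  cat(sprintf("Extended Cushing model fit (n = %d years, sqrt-scale MLE)\n",
              nrow(x$data)))
  cat(sprintf("  R = (sqrt(a*S^(gamma0 + gamma1*T)) + (sigma/2)*eps)^2\n"))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("  sigma = %.4g (%s), log-likelihood = %.4g\n",
              x$sigma, x$sigma_method, x$loglik))
  invisible(x)
}

#' @export
coef.extended_cushing_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.extended_cushing_fit <- function(object, ...) object$vcov

#' @export
residuals.extended_cushing_fit <- function(object, ...) object$residuals

#' @export
logLik.extended_cushing_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$coefficients) + 1L, class = "logLik")
}

#' Tidy an extended Cushing fit
#'
#' @param x An `extended_cushing_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `statistic`, `p.value`).
#' @method tidy extended_cushing_fit
#' @export
tidy.extended_cushing_fit <- function(x, ...) x$coefficients

#' Glance at an extended Cushing fit
#'
#' @param x An `extended_cushing_fit`.
#' @param ... Unused.
#' @return One-row tibble with `sigma`, `logLik`, `rss`, `df.residual`,
#'   `nobs`, and `r.squared` (squared correlation between observed and
#'   fitted `R`).
#' @method glance extended_cushing_fit
#' @export
glance.extended_cushing_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma,
    logLik = x$loglik,
    rss = x$rss,
    df.residual = x$df.residual,
    nobs = nrow(x$data),
    r.squared = cor(x$data$R, x$fitted)^2
  )
}

#' Augment the data of an extended Cushing fit
#'
#' @param x An `extended_cushing_fit`.
#' @param ... Unused.
#' @return The fitted year/S/R/T table with `.fitted` (median response) and
#'   `.std.resid` (standardized sqrt-scale residual) columns added.
#' @method augment extended_cushing_fit
#' @export
augment.extended_cushing_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .std.resid = x$residuals)
}
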