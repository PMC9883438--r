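test_that("shape exponent is linear in the climate covariate", {
  p <- table1_params()
  expect_equal(shape_exponent(p, 0), 0.999)
  expect_equal(shape_exponent(p, 1), 0.384)
  p0 <- extended_params(a = 10, gamma0 = 0.8, gamma1 = 0, sigma = 1)
  expect_equal(shape_exponent(p0, c(-2, 0, 3)), rep(0.8, 3))
})

test_that("median response embeds the static Cushing model", {
  p <- table1_params()
  expect_equal(median_response(p, S = 1, T = c(-1, 0, 2)), rep(p$a, 3))
  # direct high-precision evaluation of 264.299 * 500^(0.999 - 0.615*0.2)
  expect_equal(median_response(p, S = 500, T = 0.2), 61149.5469490541,
               tolerance = 1e-12)
  # gamma1 = 0 degenerates to the static model for every T
  p0 <- extended_params(a = 77, gamma0 = 1.21, gamma1 = 0, sigma = 5)
  withr::with_seed(3, {
    S <- runif(50, 1, 3000)
    T <- rnorm(50)
    expect_equal(median_response(p0, S, T), cushing_median(S, 77, 1.21))
  })
  expect_error(median_response(p, S = 0, T = 0), class = "cushingsr_error_domain")
})

test_that("recruitment rate equals the derivative of the median response", {
  p_lin <- extended_params(a = 42, gamma0 = 1, gamma1 = 0, sigma = 1)
  expect_equal(recruitment_rate(p_lin, S = c(1, 10, 500), T = 0), rep(42, 3))

  p <- table1_params()
  withr::with_seed(9, {
    S <- runif(40, 2, 2500)
    T <- runif(40, -0.3, 0.3)
    h <- 1e-5 * S
    num <- (median_response(p, S + h, T) - median_response(p, S - h, T)) / (2 * h)
    expect_equal(recruitment_rate(p, S, T), num, tolerance = 1e-6)
  })
  # warmer covariate lowers the rate at the headline parameters
  expect_lt(recruitment_rate(p, 1000, T = 0.3), recruitment_rate(p, 1000, T = -0.3))
})

test_that("simulate_response collapses to the median at sigma 0 and is seed-stable", {
  p0 <- table1_params(sigma = 0)
  S <- c(6, 100, 2728)
  T <- c(0.1, -0.2, 0)
  expect_identical(simulate_response(p0, S, T), median_response(p0, S, T))

  p <- table1_params()
  d1 <- simulate_response(p, S, T, seed = 99)
  d2 <- simulate_response(p, S, T, seed = 99)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
})

test_that("simulated draws match the closed-form moments of the noise model", {
  p <- table1_params()
  mu <- sqrt(median_response(p, S = 500, T = 0.1))
  s <- p$sigma / 2
  n <- 2e5
  draws <- withr::with_seed(123, simulate_response(p, rep(500, n), rep(0.1, n)))
  m_theory <- mu^2 + s^2
  v_theory <- 4 * mu^2 * s^2 + 2 * s^4   # = mu^2*sigma^2 + sigma^4/8
  se_mean <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - m_theory), 3 * se_mean)
  dev2 <- (draws - mean(draws))^2
  se_var <- sd(dev2) / sqrt(n)
  expect_lt(abs(var(draws) - v_theory), 3 * se_var)
})

test_that("fit_extended recovers noise-free parameters exactly", {
  truth <- extended_params(a = 264.299, gamma0 = 0.999, gamma1 = -0.615, sigma = 0)
  S <- round(6 * exp(log(2728 / 6) / 36 * 0:36))
  T <- eval_cycle(study_cycle(), 1984:2020, lag = 3)$T
  d <- noisefree_extended(truth, S, T)
  f <- fit_extended(d, tibble::tibble(year = d$year, T = T))
  expect_equal(coef(f)[["a"]], truth$a, tolerance = 1e-5)
  expect_equal(coef(f)[["gamma0"]], truth$gamma0, tolerance = 1e-7)
  expect_equal(coef(f)[["gamma1"]], truth$gamma1, tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)
  expect_equal(glance(f)$r.squared, 1, tolerance = 1e-10)
})

test_that("the optimizer beats a surrounding 4-D likelihood grid on a tiny instance", {
  cyc <- study_cycle()
  years <- 2000:2005
  T <- eval_cycle(cyc, years, lag = 3)$T
  S <- c(40, 60, 90, 140, 210, 320)
  truth <- extended_params(a = 100, gamma0 = 1.05, gamma1 = -0.5, sigma = 20)
  d <- withr::with_seed(41, tibble::tibble(
    year = years, S = S,
    R = pmax(simulate_response(truth, S, T), 1)))
  f <- fit_extended(d, tibble::tibble(year = years, T = T))

  loglik <- function(a, g0, g1, sig) {
    mu <- sqrt(a * S^(g0 + g1 * T))
    sum(dnorm(sqrt(d$R), mu, sig / 2, log = TRUE))
  }
  grid <- expand.grid(a = seq(0.5, 1.5, length.out = 11) * truth$a,
                      g0 = seq(0.85, 1.25, length.out = 11),
                      g1 = seq(-1, 0, length.out = 11),
                      sig = seq(0.4, 2, length.out = 9) * truth$sigma)
  grid_ll <- mapply(loglik, grid$a, grid$g0, grid$g1, grid$sig)
  expect_gte(f$loglik, max(grid_ll))
})

test_that("fit_extended inference output is well-formed and consistent", {
  d <- generate_dataset(synth_config(seed = 314))
  f <- fit_extended(d$abundance, d$cycle)
  td <- tidy(f)
  expect_identical(td$term, c("a", "gamma0", "gamma1"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_true(all(td$std.error > 0))
  expect_equal(td$conf.high - td$estimate, 1.96 * td$std.error, tolerance = 1e-12)
  expect_equal(td$statistic, td$estimate / td$std.error, tolerance = 1e-12)
  expect_equal(td$p.value, 2 * pt(-abs(td$statistic), df = nrow(d$abundance) - 3),
               tolerance = 1e-12)
  expect_length(residuals(f), nrow(d$abundance))
  expect_equal(f$df.residual, 34)

  # sigma conventions differ only by the RSS denominator
  f_ml <- fit_extended(d$abundance, d$cycle, sigma = "ml")
  n <- nrow(d$abundance)
  expect_equal(f_ml$sigma, f$sigma * sqrt((n - 3) / n), tolerance = 1e-12)

  aug <- augment(f)
  expect_equal(aug$.fitted, f$fitted)
})

test_that("fit_extended refuses unidentifiable designs and bad inputs", {
  d <- generate_dataset(synth_config(seed = 8))
  flat_T <- tibble::tibble(year = d$abundance$year, T = 0.1)
  expect_error(fit_extended(d$abundance, flat_T), "gamma1",
               class = "cushingsr_error_data")
  # fixing gamma1 makes the constant-T design fittable; on data generated
  # without a climate effect it recovers the static exponent
  d0 <- generate_dataset(synth_config(
    true_params = extended_params(a = 264.299, gamma0 = 0.999, gamma1 = 0, sigma = 10),
    seed = 9))
  f_fix <- fit_extended(d0$abundance, tibble::tibble(year = d0$abundance$year, T = 0.1),
                        gamma1 = 0)
  expect_identical(tidy(f_fix)$term, c("a", "gamma0"))
  expect_equal(coef(f_fix)[["gamma0"]], 0.999, tolerance = 0.01)
  expect_equal(f_fix$df.residual, nrow(d0$abundance) - 2)

  expect_error(fit_extended(d$abundance, d$cycle[-1, ]), "identical years",
               class = "cushingsr_error_data")
  expect_error(fit_extended(d$abundance[1:4, ], d$cycle[1:4, ]),
               class = "cushingsr_error_data")
})
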