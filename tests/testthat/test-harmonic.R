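test_that("fit_harmonic recovers a pure sinusoid and a constant series", {
  years <- 1900:2010
  idx <- tibble::tibble(year = years, value = sin(2 * pi * (years - 5) / 26))
  cyc <- fit_harmonic(idx, period = 26)
  expect_equal(cyc$amplitude, 1, tolerance = 1e-8)
  expect_equal(cyc$phase, 5 %% 26, tolerance = 1e-6)
  expect_equal(cyc$offset, 0, tolerance = 1e-10)
  expect_equal(cyc$r2, 1, tolerance = 1e-10)

  flat <- tibble::tibble(year = 1900:1950, value = 0.42)
  expect_warning(cyc_flat <- fit_harmonic(flat), "zero variance")
  expect_equal(cyc_flat$amplitude, 0)
  expect_equal(cyc_flat$offset, 0.42)

  expect_error(fit_harmonic(idx[1:3, ]), class = "cushingsr_error_data")
})

test_that("noisy harmonic extraction matches a dense grid search", {
  years <- 1900:2010
  truth <- list(amplitude = 0.3, phase = 9, offset = 0.05)
  idx <- withr::with_seed(31, tibble::tibble(
    year = years,
    value = truth$offset + truth$amplitude * sin(2 * pi * (years - truth$phase) / 26) +
      rnorm(111, 0, 0.1)
  ))
  cyc <- fit_harmonic(idx, period = 26)

  sse <- function(A, phi, off) {
    sum((idx$value - off - A * sin(2 * pi * (years - phi) / 26))^2)
  }
  grid <- expand.grid(A = seq(0.1, 0.5, length.out = 41),
                      phi = seq(0, 26, length.out = 131),
                      off = seq(-0.05, 0.15, length.out = 21))
  grid$sse <- mapply(sse, grid$A, grid$phi, grid$off)
  best <- grid[which.min(grid$sse), ]
  expect_equal(cyc$amplitude, best$A, tolerance = 0.011)       # grid step 0.01
  expect_equal(cyc$offset, best$off, tolerance = 0.011)
  d_phase <- min(abs(cyc$phase - best$phi), 26 - abs(cyc$phase - best$phi))
  expect_lt(d_phase, 0.21)                                     # grid step 0.2
  expect_lte(sse(cyc$amplitude, cyc$phase, cyc$offset), min(grid$sse))
})

test_that("sinusoid parameterization agrees with the sin/cos OLS closed form", {
  years <- 1920:2000
  idx <- withr::with_seed(7, tibble::tibble(
    year = years, value = 0.1 + 0.25 * sin(2 * pi * (years - 12) / 26) + rnorm(81, 0, 0.05)))
  cyc <- fit_harmonic(idx, period = 26)
  w <- 2 * pi / 26
  X <- cbind(1, sin(w * years), cos(w * years))
  beta <- solve(crossprod(X), crossprod(X, idx$value))  # closed-form OLS
  expect_equal(cyc$amplitude, sqrt(beta[2]^2 + beta[3]^2), tolerance = 1e-8)
  expect_equal(cyc$offset, beta[1], tolerance = 1e-8)
  fitted_cycle <- eval_cycle(cyc, years)$T
  expect_equal(fitted_cycle, as.numeric(X %*% beta), tolerance = 1e-8)
})

test_that("eval_cycle applies lags correctly and respects periodicity", {
  cyc <- study_cycle()
  years <- 1984:2020
  lag0 <- eval_cycle(cyc, years, lag = 0)
  lag3 <- eval_cycle(cyc, years, lag = 3)
  expect_equal(lag3$T, eval_cycle(cyc, years - 3, lag = 0)$T)
  expect_equal(eval_cycle(cyc, years, lag = 26)$T, lag0$T, tolerance = 1e-12)
  expect_error(eval_cycle(cyc, years, lag = -1), class = "cushingsr_error_parameter")
  expect_error(eval_cycle(cyc, years, lag = 2.5), class = "cushingsr_error_parameter")
})

test_that("lag_scan finds constructed direct and inverse relationships", {
  cyc <- harmonic_cycle(period = 26, amplitude = 1, phase = 5, offset = 0)
  years <- 1984:2020

  inv <- tibble::tibble(year = years, value = -eval_cycle(cyc, years, lag = 3)$T)
  s_inv <- lag_scan(inv, cyc, max_lag = 10)
  expect_equal(s_inv$best_lag, 3)
  expect_equal(s_inv$table$r[s_inv$table$lag == 3], -1, tolerance = 1e-12)
  expect_equal(s_inv$table$r2[s_inv$table$lag == 3], 1, tolerance = 1e-12)

  ident <- tibble::tibble(year = years, value = eval_cycle(cyc, years)$T)
  expect_equal(lag_scan(ident, cyc, max_lag = 10)$best_lag, 0)
})

test_that("lag_scan r2 values match the direct correlation formula on white noise", {
  cyc <- study_cycle()
  years <- 1992:2020
  target <- withr::with_seed(17, tibble::tibble(year = years, value = rnorm(29)))
  scan <- lag_scan(target, cyc, max_lag = 8)
  for (l in 0:8) {
    T_l <- cyc$offset + cyc$amplitude * sin(2 * pi * (years - l - cyc$phase) / cyc$period)
    r_direct <- sum((target$value - mean(target$value)) * (T_l - mean(T_l))) /
      sqrt(sum((target$value - mean(target$value))^2) * sum((T_l - mean(T_l))^2))
    expect_equal(scan$table$r[scan$table$lag == l], r_direct, tolerance = 1e-12)
  }
  expect_true(all(abs(scan$table$r) <= 1))
})

test_that("lag_scan is invariant to affine rescaling of the target and validates input", {
  cyc <- study_cycle()
  years <- 1984:2015
  target <- withr::with_seed(23, tibble::tibble(year = years, value = rnorm(32)))
  s1 <- lag_scan(target, cyc, max_lag = 6)
  s2 <- lag_scan(dplyr::mutate(target, value = 5 - 2.2 * value), cyc, max_lag = 6)
  expect_equal(abs(s1$table$r), abs(s2$table$r), tolerance = 1e-12)
  expect_equal(s1$table$r2, s2$table$r2, tolerance = 1e-12)
  expect_equal(s1$best_lag, s2$best_lag)

  const <- tibble::tibble(year = years, value = 1)
  expect_error(lag_scan(const, cyc, max_lag = 5), class = "cushingsr_error_data")
  expect_error(lag_scan(target, cyc, max_lag = 30), class = "cushingsr_error_parameter")
})
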