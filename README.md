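# cushingsr

Stock–recruitment analysis for recovering populations whose recruitment
regime drifts with climate. The package was built around a long annual
monitoring series of nesting sea-turtle females (`S`, the stock) and the
hatchlings they produce the same season (`R`, the recruits), but applies to
any positive annual SR series.

Three layers:

1. **Static Cushing model** `R = a·S^b`, fit by OLS on the linearization
   `ln R = ln a + b·ln S` (`fit_cushing()`), plus a sliding-window local
   regression (`local_cushing()`) that tracks drift in the shape exponent
   `b` through time, keying each window's estimate to its right endpoint.
2. **Climate cycle tools**: least-squares extraction of a fixed-period
   harmonic (default 26 years) from an annual SST-anomaly index
   (`fit_harmonic()`), lagged evaluation of the cycle as a covariate
   (`eval_cycle()`), and a lag scan maximizing squared correlation with a
   target series (`lag_scan()`).
3. **Extended Cushing model**, the core statistical contribution:

   ```
   b_t = γ0 + γ1·T_t
   R_t = ( √(a·S_t^{γ0 + γ1·T_t}) + (σ/2)·ε_t )²,   ε_t ~ iid N(0,1)
   ```

   The exponent responds linearly to the lagged climate covariate `T_t`,
   and the square-root-scale perturbation gives the response positive skew
   and a variance that grows with its median — with the classical Cushing
   curve embedded exactly at σ = 0. `fit_extended()` estimates
   `(a, γ0, γ1, σ)` by maximum likelihood (nonlinear least squares on the
   √R scale) with Wald standard errors, 95% confidence limits, t/p values;
   `median_response()`, `recruitment_rate()` (= d med(R)/dS),
   `prediction_band()` (exact quantiles of the skewed response
   distribution) and `diagnostics()` (Shapiro–Wilk, Ljung–Box on the
   standardized √-scale residuals) complete the inference. A
   synthetic-data generator (`synth_config()`, `generate_dataset()`) with
   known truth at the study's scale backs Monte-Carlo validation of the
   whole pipeline.

Everything takes and returns tibbles, pipes cleanly, and follows the
broom/ggplot2 conventions (`tidy()`, `glance()`, `augment()`,
`autoplot()`).

## Worked example

Simulate a 37-year series at the study's scale (nesters recovering
exponentially from 6 to ≈2,700; a 26-year anomaly cycle, lagged 3 years,
modulating the exponent) and run the full analysis:

```r
library(cushingsr)

cfg <- synth_config(seed = 2026)   # defaults: study-scale truth
d   <- generate_dataset(cfg)

fit <- fit_extended(d$abundance, d$cycle)
fit
#> Extended Cushing model fit (n = 37 years, sqrt-scale MLE)
#>   R = (sqrt(a*S^(gamma0 + gamma1*T)) + (sigma/2)*eps)^2
#>    term estimate std.error conf.low conf.high statistic   p.value
#>       a 233.4640  42.61976 149.9293  316.9988     5.478 4.112e-06
#>  gamma0   1.0104   0.02704   0.9574    1.0634    37.361 3.413e-29
#>  gamma1  -0.6476   0.03033  -0.7070   -0.5881   -21.349 2.837e-21
#>   sigma = 42.92 (least-squares), log-likelihood = -164.4
```

The generating truth was `a = 264.299, γ0 = 0.999, γ1 = -0.615,
σ = 50.65`: every 95% interval covers it, and `γ1` is sharply negative —
warm phases of the cycle depress the exponent. The model explains
essentially all of the variation on the original scale:

```r
glance(fit)$r.squared
#> [1] 0.9974805
```

The windowed local regression produces one estimate per 9-year window,
keyed to the right endpoint — 29 estimates for 37 years:

```r
lb <- local_cushing(d$abundance, window = 9)
nrow(lb); range(lb$year)
#> [1] 29
#> [1] 1992 2020
```

Practical consequences of the fitted climate effect: at `S = 1000`
nesters, the recruitment rate (hatchlings per additional nester) under
this replicate's estimates is about 90 at the cycle's warm peak
(`T = +0.2`) versus about 700 at its cold trough (`T = -0.2`):

```r
recruitment_rate(fit, 1000, T = 0.2)    # ~90
recruitment_rate(fit, 1000, T = -0.2)   # ~700
```

Residual diagnostics check the noise model's two assumptions; on this
particular replicate normality passes and the Ljung–Box test flags mild
serial correlation (individual replicates do so occasionally at α = 0.05):

```r
diagnostics(fit)
#> # A tibble: 2 × 4
#>   test                            statistic p.value pass
#>   <chr>                               <dbl>   <dbl> <lgl>
#> 1 normality (Shapiro-Wilk)            0.955  0.141  TRUE
#> 2 independence (Ljung-Box, lag 7)    17.9    0.0124 FALSE
```

`autoplot(fit)` draws the observed counts with the fitted median and the
95% prediction band (asymmetric, widening with the median);
`plot_local_b(lb, cycle, lag = 3)` overlays the windowed exponent on the
lagged cycle; `autoplot(lag_scan(...))` shows the lag profile.

Real data enter through `read_abundance()` (CSV with configurable column
names, validated: positive counts, strictly increasing years),
`read_climate_index()` (annual, or monthly averaged to annual) and
`read_cycle()` for a precomputed covariate series.

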