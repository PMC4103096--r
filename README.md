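# gmwmlogit

Robust estimation of baseline-category (polytomous) logistic regression
for nominal responses with continuous covariates.

Applied multinomial regressions — hypertension stage on age, BMI and
sodium intake; disease subtype on biomarkers — are routinely fit by
maximum likelihood, which is fragile: a few subjects with grossly
mis-recorded covariates or responses filed in the wrong category can flip
the sign of a slope.  This package implements a **generalized method of
weighted moments (GMWM)** estimator that bounds the influence of such
observations, alongside the MLE and standard GMM baselines, outlier
diagnostics, and a Monte Carlo harness for studying all three under
controlled contamination.

## The model and the estimator

For response categories `1..J` (category 1 the reference) and covariates
`x = (1, x_1, ..., x_p)`:

    log{ pi_j(x) / pi_1(x) } = x' beta_j ,   j = 2, ..., J.

The per-observation moment is `u_i = X_i (y_i* - pi_i)` (with `X_i` the
block design expansion and `y_i*` the indicator over categories `2..J`);
its sum is the score, so the exactly-identified GMM solving
`sum u_i = 0` equals the MLE.  The GMWM replaces each condition by

    u_i^w = w_i X_i (y_i* - pi_i) - c_i ,

where `w_i = w_d(d_i) * w_x(H_i)` combines a Huber weight
`min(1, c_d/d_i)` on the moment-based quadratic distance
`d_i = u_i' Sigma_n(beta)^{-1} u_i` (cutoff `c_d = chi2_1(0.975)/n`) with
a hard 0/1 Mallows weight on the hat-matrix leverage trace (cutoff
`c_x = 2(p+1)(J-1)/n`), and `c_i = E[w_i X_i(y_i* - pi_i) | x_i]` —
computed by exact enumeration over the `J` outcomes — recenters the
equations so the estimator stays Fisher-consistent.  The fit is a
continuous-updating loop: freeze weights at the current coefficients,
solve the recentered weighted moment equations by damped Newton, repeat.
See the methods vignette (`vignettes/gmwm-methods.Rmd`) for the
numerical choices and their rationale.

## Worked example

```r
library(gmwmlogit)

# 500 observations from the reference design, 5% of rows replaced by
# outliers (covariates near (2,3), responses deliberately misclassified)
d <- contaminate(simulate_dataset(500, seed = 42), rate = 0.05, seed = 43)

fit_mle(d)
#> Coefficients:
#>      (Intercept)      x1      x2
#> cat2      1.0725 -0.4053 -0.5467
#> cat3     -0.0713  0.4711 -0.1332

fit_gmwm(d)
#> Converged: TRUE in 9 iterations
#> Downweighted observations (w < 1): 174 ; zero-weight: 38
#> Coefficients:
#>      (Intercept)      x1      x2
#> cat2      0.9803 -0.7011 -1.1297
#> cat3     -0.0829  0.5819 -0.2816
```

The generating slopes for category 2 are `(-0.8, -1.0)`: the 25 corrupted
rows pull the MLE slopes roughly half-way to zero (`-0.41, -0.55`), while
the robust fit (`-0.70, -1.13`) stays within sampling error of the truth.
Wald inference and odds ratios:

```r
coefficient_table(fit_gmwm(d), sided = "two")
#>   parameter estimate     se p_value odds_ratio or_lower or_upper
#> 1    beta20   0.9803 0.1486  0.0000     2.6653   1.9918   3.5665
#> 2    beta21  -0.7011 0.1775  0.0001     0.4960   0.3503   0.7024
#> 3    beta22  -1.1297 0.1751  0.0000     0.3231   0.2293   0.4554
#> ...
```

Outlier diagnostics (distances vs leverages, the data behind a
distance-leverage scatter plot):

```r
outlier_report(fit_gmwm(d))
#> Outlier report: c_d = 0.01005 , c_x = 0.024
#> 168 distance-flagged, 40 leverage-flagged of 500 observations
```

A Monte Carlo comparison in the style of the package's validation study:

```r
run_monte_carlo(n = 1000, n_reps = 200, contamination_rate = 0.05, seed = 5)
#>    estimator parameter true    bias    mse coverage
#> 3        MLE    beta22 -1.0  0.4668 0.2238    0.000
#> 9       GMWM    beta22 -1.0  0.0507 0.0149    0.960
#> ...
```

Under 5% contamination the MLE slope estimate for the second covariate is
biased by ~0.47 and its nominal-95% intervals never cover the truth; the
GMWM bias is an order of magnitude smaller with calibrated coverage.

Command-line wrappers live in `inst/scripts/` (`plrm-fit.R`,
`plrm-simulate.R`), and `make_survey_fixture()` generates a synthetic
four-category hypertension-style survey for application-shaped demos.

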