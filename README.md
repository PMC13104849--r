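# lrho — regression modeling of Spearman's rho for longitudinal data

`lrho` estimates and tests Spearman's rank correlation between two
longitudinal outcomes — for example a metabolite level and an anxiety score
measured at the same visits — as a *regression*: the correlation may change
over time, differ between covariate-defined groups, and the data may have
monotone missing-at-random (MAR) dropout. It is aimed at biostatisticians
running longitudinal biomarker/symptom association screens where
cross-sectional rank correlations per visit would ignore the longitudinal
structure, covariates, and missingness.

## The model in brief

The population Spearman correlation can be written through a three-subject
concordance kernel,

    phi(z_i, z_j, z_k) = I(u_j < u_i) I(v_k < v_i),     rho = 12 E[phi] - 3,

so the triplet-level response `f_it = 12 phi(z_it, z_jt, z_kt) - 3` has
conditional mean `rho` and can be regressed on visit indicators and
triplet-level covariates through the Fisher-z-type link
`g(rho) = log((1+rho)/(1-rho))` — a functional response model. Coefficients
solve U-statistics based generalized estimating equations (UGEE) over all
n-choose-3 subject triplets, with a U-statistic sandwich covariance
(`Sigma = 9 B^-1 Sigma_w B^-T`). Under monotone MAR dropout, a jointly
estimated sequential-logistic dropout model supplies inverse-probability
weights (UWGEE), and the joint sandwich propagates the dropout-model
uncertainty into the correlation SEs. An MCAR diagnostic (Wald tests of the
outcome slopes in the dropout model) drives an automatic choice between the
unweighted complete-pair and the weighted analysis. Two-stage screening
(liberal p < 0.2 filter, then Bonferroni within the retained set) supports
many-feature workflows. Details and design choices are in the vignette
(`vignettes/longitudinal-spearman.Rmd`).

## Worked example

Simulate the package's reference design — 50 subjects, 3 visits, bivariate
normal outcomes with within-visit correlation 0.5 (true Spearman rho 0.483
at every visit, true baseline coefficient 1.053), then impose calibrated
MAR dropout targeting 85% / 75% observation at visits 2 and 3 — and fit the
visit-indicator model:

```r
library(lrho)
design <- lrho_design(n = 50, m = 3, seed = 2026,
                      dropout = list(targets = c(0.85, 0.75)))
cal <- calibrate_dropout_intercepts(design)
round(cal, 3)
#> gamma20 gamma30
#>   0.555   0.787

dat <- simulate_mar_dropout(simulate_complete(design), attr(cal, "gamma"),
                            seed = 2027)
dat
#> Longitudinal bivariate dataset: 50 subjects x 3 visits
#>   observed proportion by visit: 1.000 0.860 0.760
#>   missingness pattern: monotone

fit <- lrho_fit(dat, lrho_spec(visits = 3, builders = list("visit_indicator")),
                missing = "auto")
fit
#> Longitudinal Spearman correlation regression (UWGEE, IPW)
#> n = 50 subjects, 3 visits, 19,600 triplets
#>                      estimate     se      z      p
#> (Intercept)            1.2426 0.3111 3.9949 0.0001
#> visit2                 0.4623 0.4416 1.0470 0.2951
#> visit3                 0.5407 0.4719 1.1459 0.2519
#> gamma.t2.(Intercept)   0.7226 0.5548 1.3023 0.1928
#> gamma.t2.u1            1.8980 0.9582 1.9808 0.0476
#> ...
#> correlation profile: t1=0.552 t2=0.692 t3=0.712
```

Reading the output: the intercept is the baseline log-odds-type correlation
(`h(1.243) = 0.552` is the fitted baseline Spearman rho; the truth here is
0.483 and the 95% interval below covers it), `visit2`/`visit3` are changes
from baseline on the link scale (truth 0; not significant), and the
`gamma.*` rows are the dropout model — the MCAR test rejected, so the
weighted analysis was used and dropout at visit 2 visibly loads on the
prior metabolite value `u1`.

```r
round(rho_ci(fit, visit = 1), 3)
#>   rho lower upper
#> 0.552 0.306 0.729
wald_test(fit, c("visit2", "visit3"))   # H0: no temporal change
#> Wald test: chi^2 = 1.5405, df = 2, p = 0.4629
```

Monte Carlo reproduction of the published operating characteristics
(desk-scale, M = 200):

```r
run_monte_carlo(lrho_design(n = 50, M = 200, seed = 1), estimator = "ugee")
```

A thin command-line front end over the same functions lives at
`inst/cli/lrho.R` (`fit`, `mcar-test`, `simulate`, `screen` subcommands
with a YAML model config).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the simulation quantities the package is validated against: the
Monte Carlo means of the baseline coefficient, its sandwich SE and the
fitted baseline correlation under the complete-data and MAR-dropout designs
at n = 50 (M = 200), the calibrated dropout intercepts on a 50,000-subject
cohort, and the realized visit-2 observation rate. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
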