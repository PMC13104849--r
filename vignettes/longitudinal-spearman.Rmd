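---
title: "Modeling longitudinal Spearman correlations with lrho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal Spearman correlations with lrho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrho)
```

## The problem

Longitudinal biomarker studies — the motivating setting is metabolomic
profiling alongside repeated psychological assessments in breast-cancer
patients under chemotherapy — often ask how the *association* between two
outcomes evolves over time, and whether it differs between subgroups.
Spearman's rank correlation is the natural association measure when
relationships are monotone but not linear, yet classical estimators are
cross-sectional: they produce one number per time point, cannot adjust for
covariates, and ignore dropout. `lrho` implements a regression framework for
Spearman's rho in longitudinal bivariate data with monotone
missing-at-random (MAR) dropout.

## Model

For subject $i$ at visit $t$, let $z_{it} = (u_{it}, v_{it})^\top$ be the
bivariate outcome. The population Spearman correlation (grade correlation)
can be written through a three-subject concordance kernel
$$
\phi(z_i, z_j, z_k) = I(u_j < u_i)\, I(v_k < v_i), \qquad
\rho = 12\, E[\phi] - 3 .
$$
This identity is the bridge to regression: define the triplet-level
functional response $f_{\mathbf{i}t} = 12\,\phi(z_{it}, z_{jt}, z_{kt}) - 3$
for each combination $\mathbf{i} = \{i<j<k\}$ and model its conditional mean
$$
E[f_{\mathbf{i}t} \mid x_{\mathbf{i}t}]
  = h\!\left(\beta^\top \xi(x_{\mathbf{i}t})\right), \qquad
h(\eta) = \frac{e^\eta - 1}{e^\eta + 1},
$$
a functional response model (FRM): the "response" involves three subjects'
outcomes, and the Fisher-z-type link $g = h^{-1}$ keeps the modeled
correlation inside $(-1, 1)$. Triplet-level covariates $\xi$ are built from
the subjects' own covariates: visit indicators; the mean or median of a
continuous covariate over the triplet; and, for a binary group, the
partition indicators (all three in group 0 / all in group 1 / mixed), or
their contrast parameterization so that "equal correlation in both groups"
is a single coefficient test.

Since $\phi$ is not symmetric in its three arguments, the package averages
it over all six orderings of each combination (the default). Both choices
estimate the same $\rho$ — the expectation is invariant under permutation of
i.i.d. subjects — but the symmetrized kernel has smaller variance and makes
the response independent of the arbitrary storage order of a combination.

## Estimation

With $S_\mathbf{i} = f_\mathbf{i} - h_\mathbf{i}(\beta)$ stacked over
visits, $\beta$ solves the U-statistics based generalized estimating
equations (UGEE)
$$
U(\beta) \;=\; \sum_{\mathbf{i} \in C^n_3}
  D_\mathbf{i} V_\mathbf{i}^{-1} S_\mathbf{i} \;=\; 0,
$$
summing over all $\binom{n}{3}$ triplets rather than over subjects;
$D_\mathbf{i} = \partial h_\mathbf{i} / \partial \beta$ and
$V_\mathbf{i} = A^{1/2} R(\alpha) A^{1/2}$ is a working covariance with
working correlation $R$ (independence by default, exchangeable optional
with a moment estimate of $\alpha$ refreshed each iteration). The solver is
Gauss–Newton with step halving; when no shortened step reduces
$\|U\|_\infty$ the full Newton step is retained, because the Gauss–Newton
direction often overshoots transiently on ill-conditioned covariate designs
yet still converges.

Standard errors come from the U-statistic sandwich
$\hat\Sigma_\beta = 9 \hat B^{-1} \hat\Sigma_w \hat B^{-\top}$ with
$\hat B$ the average of $D V^{-1} D^\top$ over triplets and $\hat\Sigma_w$
built from per-subject projections $\hat w_i$ (each subject's average
estimating-function contribution over the $\binom{n-1}{2}$ completions of
its triplets); $\widehat{\mathrm{Var}}(\hat\beta) = \hat\Sigma_\beta / n$.
The factor 9 is the squared kernel order of the underlying third-order
U-statistic.

### A working-variance correction

The natural per-visit variance printed for this model,
$A_{\mathbf{i}t} = h(1-h)$, is negative whenever the modeled correlation is
negative. Because $f = 12\phi - 3$ with $\phi$ Bernoulli of mean
$(h+3)/12$, the implied conditional variance is
$(h+3)(9-h) > 0$ for all $h \in (-1,1)$, and that is what the package uses.
The working variance affects efficiency only, never consistency, but the
positive form is required for the weighting to be defined at negative
correlations.

### Missing data

Under monotone dropout (baseline complete; once missing, always missing),
a sequential logistic model
$\mathrm{logit}\, p_{it} = \gamma_{t0} + \gamma_{t1} u_{i,t-1} + \gamma_{t2} v_{i,t-1}$
describes the probability of remaining observed; cumulative products give
$\pi_{it}$. The weighted equations (UWGEE) multiply each triplet-visit
residual by $\prod_{l \in \{i,j,k\}} r_{lt} / \pi_{lt}$, which restores the
unconditional kernel mean under MAR. The $\gamma$ block of the joint system
does not involve $\beta$, so it is solved first, per transition, from its
own triplet-level estimating equations (Fisher scoring started at the
logistic MLE), then $\beta$ given the weights — block-triangular, no outer
iteration needed. The joint sandwich stacks both blocks so the reported
SEs reflect that the weights were estimated.

Testing $\gamma_{t1} = \gamma_{t2} = 0$ (per transition and jointly) is the
MCAR diagnostic: `missing = "auto"` in `lrho_fit()` runs it and uses the
unweighted complete-pair analysis when the joint p-value exceeds 0.05
(configurable), the weighted analysis otherwise — mirroring the screening
workflow where each feature is first checked for outcome-dependent dropout.

Numerical safeguards, chosen once:

* estimated $\pi$ below 0.01 are truncated (weight stabilization; the
  theory is silent on extreme weights, and a single near-zero probability
  would otherwise dominate the equations);
* with very few dropout events a transition can be separated
  (the logistic likelihood has no finite maximum). The default is an error
  with guidance; `on_separation = "firth"` substitutes Firth's bias-reduced
  estimate, which is finite under separation — the Monte Carlo harness uses
  this, since at $n = 50$ roughly 6% of replicates separate by chance;
* non-monotone records are rejected by default; opt-in truncation at the
  first missing visit is available and reports how many observations it
  discarded.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `working_correlation` | independence | efficiency only; exchangeable estimates one $\alpha$ by moments |
| `tol` | 1e-9 | on $\|U\|_\infty$ scaled by $\binom{n}{3}$; tight enough that the fitted correlation matches the U-statistic oracle to 1e-6 |
| `max_iter` | 50 | Newton iterations (quadratic convergence; typically 3–8) |
| `weight_floor` | 0.01 | lower truncation of $\hat\pi$ |
| `mcar_level` | 0.05 | MCAR-vs-MAR branch threshold in `auto` |
| `stage1_threshold` | 0.2 | liberal first-stage p-value filter in screening |
| `subsample` | off | seeded triplet subsampling for very large $n$ (> 400); an approximation, never used in validation |

## What the simulator emulates

`lrho_design()` / `simulate_complete()` draw
$z_i = (u_1, v_1, \dots, u_m, v_m) \sim N(\mu, \Sigma)$ with unit variances,
within-time correlation $\delta$ (0.5 by default, possibly visit-specific)
and a common between-time correlation $\phi$ (0.25) for all cross-time
pairs. The implied true Spearman correlation per visit is
$(6/\pi)\arcsin(\delta_t/2)$ — about 0.483 at $\delta = 0.5$ — giving the
true baseline coefficient $g(0.483) \approx 1.053$. MAR dropout thins
visits 2 and 3 by sequential logistic models with unit slopes on the prior
pair; the intercepts are calibrated by bisection on a 50,000-subject cohort
so the expected observation rates hit 85% and 75% (reproducing intercepts
near 0.541 and 0.799). Default Monte Carlo size is the desk-scale
$M = 200$ (Monte Carlo SE on the mean baseline coefficient
$\approx 0.31/\sqrt{200} \approx 0.022$); the full-scale profile used for
the published tables is $M = 1000$.

What the generator does *not* emulate: non-normal margins (irrelevant to
the truth of rank correlations — any monotone transform leaves $\rho$
unchanged, which the tests exploit as an invariance check), ties
(outcomes are continuous; real assay data with detection limits would need
the tie conventions below), covariate-dependent correlation structure, and
non-monotone intermittent missingness. A green simulation test therefore
establishes correctness of the estimating equations and their calibration
under the stated data-generating process, not robustness to dropout-model
misspecification (a doubly robust extension is out of scope).

## Ties and other numerics

The concordance kernel uses strict inequalities; with continuous data ties
have probability zero, and the estimator warns when it meets them. An
opt-in deterministic jitter (seeded, magnitude $10^{-9}$ times the data
scale) breaks ties reproducibly; a principled tie-corrected kernel is
deliberately not implemented. The inverse link is evaluated as
$\tanh(\eta/2)$, which saturates smoothly without overflow; confidence
intervals for $\rho$ are computed on the $\eta$ scale and mapped through
$h$, so they always respect $(-1, 1)$. Combinations are enumerated in
lexicographic $i<j<k$ order in compiled code; the per-triplet kernel is
recomputed per pass rather than cached (memory stays $O(n)$ even at
$n = 500$, where one pass visits 20.7 million triplets).

## Design choices that were genuinely open

* **Symmetrization** of the kernel over the six orderings: on by default
  (variance reduction; order invariance), with the raw kernel available in
  `triplet_kernel()` for study.
* **Mixed-group triplets** (members from both levels of a binary
  covariate): included by default with their own indicator, matching the
  displayed three-indicator construction; `include_mixed_triplets = FALSE`
  drops them and the corresponding column, the alternative model form.
* **Intercept handling**: an explicit intercept is always included except
  when the equality-partition builder is present (its three indicators sum
  to one); the design matrix rank is checked on a sample of triplet rows
  and rank deficiency is an error, not a silent drop.
* **Initialization** from per-visit complete-case classic Spearman
  estimates mapped through $g$ (covariate coefficients at zero) — close
  enough that the solver typically converges in a handful of steps.
* **Screening** uses the two-stage procedure as a fixed pipeline: liberal
  filter at raw $p < 0.2$ on the coefficient of interest, Bonferroni within
  the retained set; features are ranked for reporting by the mean absolute
  fitted correlation across visits.

## Known limitations

* Cost is $O(n^3 m)$ per iteration; practical to $n \approx 500$ in
  compiled code, beyond which the seeded subsampling approximation is the
  intended escape hatch.
* Categorical covariates with more than two levels are not supported (the
  partition construction is binary); recode or dichotomize.
* The dropout model must be correctly specified for consistency under MAR;
  only prior outcomes enter by default (`lags = 1`, matching the
  generating model of the simulations), full history is available.
* Small-sample inference is Wald-type with no degrees-of-freedom
  correction; at $n = 50$ the simulations show close-to-nominal size, but
  very small $n$ with many covariates is untested territory.
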