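#' Spearman correlation of a bivariate normal pair
#'
#' The population (grade) Spearman correlation implied by a bivariate normal
#' Pearson correlation `r`: `(6/pi) * asin(r/2)`. Used to compute the
#' true values in the simulation designs (a Pearson correlation of 0.5
#' gives about 0.483).
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @return Spearman correlation(s).
#' @export
normal_spearman <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(abs(r) > 1))
    stop("'r' must lie in [-1, 1]")
  (6 / pi) * asin(r / 2)
}

#' Correlation matrix for the longitudinal bivariate normal design
#'
#' Builds the `2m x 2m` correlation matrix of
#' `(u_1, v_1, ..., u_m, v_m)` with unit variances, within-time `u`-`v`
#' correlation `delta` (possibly visit-specific) and a common between-time
#' correlation `phi` for all cross-time pairs (`u_s,u_t`, `v_s,v_t` and
#' `u_s,v_t` with `s != t`).
#'
#' @param delta Within-time correlation(s); scalar or length-`m` vector.
#' @param phi Between-time correlation.
#' @param m Number of visits.
#' @return Positive definite `2m x 2m` matrix (error if not).
#' @export
make_sigma <- function(delta = 0.5, phi = 0.25, m = 3L) {
  m <- as.integer(m)
  delta <- rep_len(delta, m)
  if (any(abs(delta) >= 1) || abs(phi) >= 1)
    stop("'delta' and 'phi' must lie in (-1, 1)")
  S <- matrix(phi, 2L * m, 2L * m)
  diag(S) <- 1
  for (t in seq_len(m)) {
    iu <- 2L * t - 1L; iv <- 2L * t
    S[iu, iv] <- S[iv, iu] <- delta[t]
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("correlation parameters do not give a positive definite matrix")
  dimnames(S) <- list(paste0(c("u", "v"), rep(seq_len(m), each = 2)),
                      paste0(c("u", "v"), rep(seq_len(m), each = 2)))
  S
}

#' Define a simulation design
#'
#' Describes the data-generating mechanism of the Monte Carlo experiments:
#' `n` subjects with `z_i = (u_1, v_1, ..., u_m, v_m) ~ N(mu, Sigma)`,
#' `Sigma` from [make_sigma()], and (optionally) sequential-logistic
#' missing-at-random dropout on the prior `(u, v)` pair. The implied true
#' coefficients of the visit-indicator model are
#' `beta_1 = g(normal_spearman(delta_1))` and
#' `beta_t = g(normal_spearman(delta_t)) - beta_1`.
#'
#' @param n Subjects per replicate.
#' @param m Visits.
#' @param mu Mean (scalar, recycled).
#' @param delta Within-time correlation(s).
#' @param phi Between-time correlation.
#' @param dropout `NULL` for complete data, or a list with either `gamma`
#'   (list of per-transition coefficient vectors `c(intercept, u-slope,
#'   v-slope)`) or `targets` (cumulative observation rates at visits
#'   `2..m`, intercepts to be calibrated) and `slopes` (outcome slopes,
#'   default 1).
#' @param M Monte Carlo replicates (desk-scale default 200; the full-scale
#'   profile uses 1000).
#' @param seed Master seed.
#' @return An object of class `"lrho_design"`.
#' @export
lrho_design <- function(n = 50L, m = 3L, mu = 1, delta = 0.5, phi = 0.25,
                        dropout = NULL, M = 200L, seed = 1L) {
  sigma <- make_sigma(delta, phi, m)
  delta <- rep_len(delta, m)
  rho_true <- normal_spearman(delta)
  beta_true <- c(link_g(rho_true[1]),
                 if (m > 1) link_g(rho_true[-1]) - link_g(rho_true[1]))
  if (!is.null(dropout)) {
    if (is.null(dropout$slopes)) dropout$slopes <- 1
    if (is.null(dropout$gamma) && is.null(dropout$targets))
      stop("'dropout' needs 'gamma' or 'targets'")
    if (!is.null(dropout$targets) && length(dropout$targets) != m - 1L)
      stop("'targets' must give cumulative observation rates for visits 2..m")
  }
  structure(list(n = as.integer(n), m = as.integer(m),
                 mu = rep_len(mu, 2L * m), sigma = sigma,
                 delta = delta, phi = phi,
                 rho_true = rho_true, beta_true = beta_true,
                 dropout = dropout, M = as.integer(M),
                 seed = as.integer(seed)),
            class = "lrho_design")
}

#' @export
print.lrho_design <- function(x, ...) {
  cat("Simulation design: n =", x$n, ", m =", x$m,
      ", delta =", paste(unique(x$delta), collapse = "/"),
      ", phi =", x$phi, "\n")
  cat("  true rho by visit:", paste(sprintf("%.3f", x$rho_true), collapse = " "), "\n")
  if (!is.null(x$dropout)) {
    if (!is.null(x$dropout$gamma))
      cat("  dropout intercepts:",
          paste(sprintf("%.3f", vapply(x$dropout$gamma, `[`, 0, 1L)),
                collapse = " "), "\n")
    else cat("  dropout targets:",
             paste(x$dropout$targets, collapse = " "), "(to calibrate)\n")
  } else cat("  complete data\n")
  invisible(x)
}

#' Simulate one complete-data replicate
#'
#' Draws `n` i.i.d. multivariate normal subjects from the design and reshapes
#' them into a [lrho_data()]. Reproducible: the same `(design, seed)` always
#' yields the same dataset.
#'
#' @param design A [lrho_design()].
#' @param seed Seed for this draw (default the design's master seed).
#' @return A complete [lrho_data()].
#' @export
simulate_complete <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "lrho_design"))
  rng <- get_rng_state(); on.exit(restore_rng_state(rng))
  set.seed(seed)
  z <- MASS::mvrnorm(design$n, mu = design$mu, Sigma = design$sigma)
  ui <- seq(1L, 2L * design$m, by = 2L)
  lrho_data(u = z[, ui, drop = FALSE], v = z[, ui + 1L, drop = FALSE])
}

#' Calibrate dropout-model intercepts to target observation rates
#'
#' With the outcome slopes fixed, finds the per-transition intercepts
#' `gamma_t0` such that the mean cumulative observation probability
#' `mean(pi_t)` over a large simulated cohort equals the target rate at each
#' visit, by sequential one-dimensional bisection (transition 2 first, then 3
#' given 2, and so on).
#'
#' @param design A [lrho_design()] (its `dropout$targets` and
#'   `dropout$slopes` are used unless overridden).
#' @param targets Cumulative observation rates for visits `2..m`.
#' @param slopes Outcome slopes (scalar, applied to both prior `u` and `v`).
#' @param solver_n Cohort size for the calibration (default 50000).
#' @param seed Seed for the cohort draw.
#' @param tol Tolerance on the achieved rate (default 1e-4).
#' @return Named vector of intercepts, with attributes `gamma` (the full
#'   per-transition coefficient list, ready for [simulate_mar_dropout()])
#'   and `rates` (achieved expected rates).
#' @export
calibrate_dropout_intercepts <- function(design,
                                         targets = design$dropout$targets,
                                         slopes = design$dropout$slopes,
                                         solver_n = 50000L, seed = design$seed,
                                         tol = 1e-4) {
  stopifnot(inherits(design, "lrho_design"))
  if (is.null(targets)) stop("no target rates given")
  if (any(targets >= 1 | targets <= 0))
    stop("target rates must lie strictly inside (0, 1)")
  if (is.null(slopes)) slopes <- 1
  m <- design$m
  if (length(targets) != m - 1L) stop("need one target per visit 2..m")
  cohort <- simulate_complete(
    lrho_design(n = solver_n, m = m, mu = design$mu[1], delta = design$delta,
                phi = design$phi), seed = seed)
  pi_prev <- rep(1, solver_n)
  g0 <- numeric(m - 1L)
  rates <- numeric(m - 1L)
  gamma <- vector("list", m - 1L)
  for (t in 2:m) {
    lp0 <- slopes * cohort$u[, t - 1] + slopes * cohort$v[, t - 1]
    f <- function(g) mean(pi_prev * stats::plogis(g + lp0)) - targets[t - 1L]
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0)
      stop("target rate ", targets[t - 1L],
           " cannot be bracketed at transition to visit ", t)
    repeat {                               # bisection to 'tol' on the rate
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < tol || hi - lo < 1e-12) break
      if (fm > 0) hi <- mid else lo <- mid
    }
    g0[t - 1L] <- mid
    rates[t - 1L] <- fm + targets[t - 1L]
    gamma[[t - 1L]] <- c(mid, slopes, slopes)
    pi_prev <- pi_prev * stats::plogis(mid + lp0)
  }
  names(g0) <- paste0("gamma", 2:m, "0")
  names(gamma) <- paste0("t", 2:m)
  structure(g0, gamma = gamma, rates = rates)
}

#' Impose sequential missing-at-random dropout
#'
#' Thins a complete dataset with the monotone sequential-logistic mechanism:
#' baseline always observed; a subject observed at `t - 1` remains observed
#' at `t` with probability `expit(gamma_t0 + gamma_t1 u_{t-1} + gamma_t2
#' v_{t-1})`; once missing, missing forever.
#'
#' @param data A complete [lrho_data()].
#' @param gamma List of per-transition coefficient vectors
#'   `c(intercept, u-slope, v-slope)` for visits `2..m` (e.g. the `gamma`
#'   attribute of [calibrate_dropout_intercepts()]).
#' @param seed Seed for the Bernoulli draws.
#' @return A [lrho_data()] with monotone missingness.
#' @export
simulate_mar_dropout <- function(data, gamma, seed = 1L) {
  stopifnot(inherits(data, "lrho_data"))
  n <- n_subjects(data); m <- n_visits(data)
  if (length(gamma) != m - 1L) stop("need one gamma per visit 2..m")
  rng <- get_rng_state(); on.exit(restore_rng_state(rng))
  set.seed(seed)
  r <- matrix(1, n, m)
  for (t in 2:m) {
    g <- gamma[[t - 1L]]
    pr <- stats::plogis(g[1] + g[2] * data$u[, t - 1] + g[3] * data$v[, t - 1])
    r[, t] <- r[, t - 1] * stats::rbinom(n, 1L, ifelse(is.na(pr), 0, pr))
  }
  u <- data$u; v <- data$v
  u[r == 0] <- NA_real_; v[r == 0] <- NA_real_
  lrho_data(u, v, covariates = data$covariates, subjects = data$subjects,
            visit_labels = data$visit_labels)
}

#' Monte Carlo evaluation of the estimators
#'
#' Runs `M` seeded replicates of a simulation design, fits the
#' visit-indicator model each time with the chosen estimator, and aggregates
#' in the layout of the simulation tables: mean estimate, mean asymptotic
#' (sandwich) SE, empirical SE and mean fitted correlation per visit, plus
#' rejection rates for the no-temporal-change hypotheses
#' (`beta_t = 0` for each `t >= 2`, and jointly).
#'
#' Replicate `r` uses the `r`-th element of a seed stream drawn from the
#' master seed, so reducing `M` keeps the per-replicate data unchanged.
#' Replicates whose fit fails or does not converge are dropped and counted;
#' more than 5 percent failures is an error.
#'
#' @param design A [lrho_design()]; its `dropout` element must be set for the
#'   `"uwgee"` and `"complete_case"` estimators (intercepts are calibrated
#'   first if only targets are given).
#' @param estimator `"ugee"` (complete data), `"uwgee"` (weighted, MAR) or
#'   `"complete_case"` (unweighted complete-pair under dropout).
#' @param M,seed Override the design's replicate count / master seed.
#' @param level Test size for the rejection rates (default 0.05).
#' @param se Compute sandwich SEs per replicate (default `TRUE`).
#' @return An object of class `"lrho_mc"`: `estimates` (one row per
#'   coefficient), `rho` (mean fitted correlation per visit), `rejection`
#'   (named rates), `n_failed`, `M`, and the realized observation rates per
#'   visit under dropout.
#' @export
run_monte_carlo <- function(design, estimator = c("ugee", "uwgee", "complete_case"),
                            M = design$M, seed = design$seed, level = 0.05,
                            se = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(design, "lrho_design"))
  m <- design$m
  spec <- lrho_spec(visits = m, builders = list("visit_indicator"))
  gamma <- NULL
  if (estimator != "ugee") {
    if (is.null(design$dropout)) stop("design has no dropout mechanism")
    gamma <- design$dropout$gamma
    if (is.null(gamma))
      gamma <- attr(calibrate_dropout_intercepts(design, seed = seed), "gamma")
  }
  rng <- get_rng_state(); on.exit(restore_rng_state(rng))
  set.seed(seed)
  seeds <- sample.int(2147483646L, 2L * M)
  cn <- c("(Intercept)", if (m > 1) paste0("visit", 2:m))
  est <- ase <- matrix(NA_real_, M, length(cn), dimnames = list(NULL, cn))
  rho <- matrix(NA_real_, M, m)
  rej <- matrix(NA, M, if (m > 1) m else 0)
  if (m > 1) colnames(rej) <- c(paste0("visit", 2:m), "joint")
  obs_rate <- matrix(NA_real_, M, m)
  failed <- 0L
  for (r in seq_len(M)) {
    dat <- simulate_complete(design, seed = seeds[r])
    if (estimator != "ugee")
      dat <- simulate_mar_dropout(dat, gamma, seed = seeds[M + r])
    obs_rate[r, ] <- colMeans(dat$robs)
    fit <- tryCatch(suppressWarnings(
      lrho_fit(dat, spec,
               missing = switch(estimator, ugee = "none", uwgee = "mar",
                                complete_case = "mcar"),
               on_separation = "firth", se = se)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
    est[r, ] <- fit$beta
    if (se) {
      ase[r, ] <- fit$se[seq_len(length(cn))]
      if (m > 1) {
        for (t in 2:m)
          rej[r, t - 1L] <- wald_test(fit, paste0("visit", t))$p < level
        rej[r, m] <- wald_test(fit, paste0("visit", 2:m))$p < level
      }
    }
    rho[r, ] <- fit$rho
  }
  if (failed > 0.05 * M)
    stop("Monte Carlo: ", failed, " of ", M, " replicates failed")
  ok <- !is.na(est[, 1])
  estimates <- data.frame(
    coefficient = cn,
    true = design$beta_true,
    mean_est = colMeans(est[ok, , drop = FALSE]),
    mean_ase = if (se) colMeans(ase[ok, , drop = FALSE]) else NA_real_,
    emp_se = apply(est[ok, , drop = FALSE], 2, stats::sd))
  rownames(estimates) <- NULL
  structure(list(estimates = estimates,
                 rho = stats::setNames(colMeans(rho[ok, , drop = FALSE]),
                                       paste0("t", seq_len(m))),
                 rho_true = design$rho_true,
                 rejection = if (se && m > 1)
                   colMeans(rej[ok, , drop = FALSE]) else NULL,
                 n_failed = failed, M = M, M_effective = sum(ok),
                 obs_rate = colMeans(obs_rate[ok, , drop = FALSE]),
                 estimator = estimator, design = design),
            class = "lrho_mc")
}

#' @export
print.lrho_mc <- function(x, ...) {
  cat("Monte Carlo summary (", x$estimator, ", M = ", x$M_effective,
      " of ", x$M, " replicates)\n", sep = "")
  df <- x$estimates
  df$mean_rho <- x$rho[seq_len(nrow(df))]
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  if (!is.null(x$rejection)) {
    cat("rejection rates at nominal 0.05:\n")
    print(round(x$rejection, 3))
  }
  if (x$estimator != "ugee")
    cat("mean observation rates:",
        paste(sprintf("%.3f", x$obs_rate), collapse = " "), "\n")
  invisible(x)
}
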