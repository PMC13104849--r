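test_that("single-visit intercept-only fit reproduces the U-statistic estimate", {
  sp1 <- lrho_spec(visits = 1)
  for (seed in 1:4) {
    dat <- sim_fixture(n = 30, m = 1, seed = seed)
    fit <- lrho_fit(dat, sp1)
    expect_true(fit$converged)
    expect_equal(unname(fit$rho), ustat_spearman(dat$u[, 1], dat$v[, 1]),
                 tolerance = 1e-6)
  }
})

test_that("visit-indicator fit equals the per-visit U-statistic Spearman", {
  dat <- sim_fixture(n = 45, seed = 8)
  fit <- lrho_fit(dat, visit_spec())
  for (t in 1:3)
    expect_equal(unname(fit$rho[t]),
                 ustat_spearman(dat$u[, t], dat$v[, t]), tolerance = 1e-6)
  ## same identity restricted to complete cases under complete-pair analysis
  datm <- simulate_mar_dropout(dat, list(c(1.5, 0.3, 0.3), c(1.5, 0.3, 0.3)),
                               seed = 9)
  fitc <- lrho_fit(datm, visit_spec(), missing = "mcar")
  for (t in 2:3) {
    ok <- datm$robs[, t] == 1
    expect_equal(unname(fitc$rho[t]),
                 ustat_spearman(datm$u[ok, t], datm$v[ok, t]),
                 tolerance = 1e-6)
  }
})

test_that("independent outcomes give near-zero coefficients and valid tests", {
  dat <- simulate_complete(lrho_design(n = 80, delta = 0, phi = 0), seed = 14)
  fit <- lrho_fit(dat, visit_spec())
  expect_lt(abs(fit$beta[1]), 0.35)          # ~2.5 SE at n = 80
  expect_lt(abs(fit$rho[1]), 0.2)
})

test_that("sandwich covariance is symmetric positive semidefinite and scales with n", {
  dat <- sim_fixture(n = 50, seed = 21)
  fit <- lrho_fit(dat, visit_spec())
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_true(all(fit$se > 0.05 & fit$se < 1))
  dat2 <- sim_fixture(n = 150, seed = 21)
  fit2 <- lrho_fit(dat2, visit_spec())
  expect_lt(fit2$se[1], fit$se[1])           # larger n, smaller SE
})

test_that("estimating function is zero at the solution", {
  dat <- sim_fixture(n = 35, seed = 30)
  fit <- lrho_fit(dat, visit_spec())
  expect_lt(fit$unorm, 1e-6)
})

test_that("exchangeable working correlation gives the same saturated fit", {
  dat <- sim_fixture(n = 40, seed = 17)
  f1 <- lrho_fit(dat, visit_spec())
  f2 <- lrho_fit(dat, visit_spec(working_correlation = "exchangeable"))
  ## visit-saturated model: the solution zeroes each visit's residual sum,
  ## so the working correlation cannot move the point estimates
  expect_equal(f1$beta, f2$beta, tolerance = 1e-5)
  expect_true(is.numeric(f2$alpha) && abs(f2$alpha) < 1)
  expect_null(f1$alpha)
})

test_that("covariate builders shift the linear predictor as constructed", {
  set.seed(33)
  dat <- sim_fixture(n = 50, seed = 33)
  dat$covariates <- data.frame(grp = rbinom(50, 1, 0.5))
  spg <- lrho_spec(3, list("visit_indicator",
                           list(kind = "group_contrast", column = "grp")))
  fit <- lrho_fit(dat, spg)
  expect_true(fit$converged)
  expect_named(coef(fit), c("(Intercept)", "visit2", "visit3",
                            "grp.diff", "grp.mixed"))
  ## group label is independent of the outcomes: contrast should be small
  expect_lt(abs(coef(fit)["grp.diff"]),
            4 * fit$se["grp.diff"])
  ## excluding mixed triplets drops the mixed column and still converges
  spx <- lrho_spec(3, list("visit_indicator",
                           list(kind = "categorical_equality", column = "grp")),
                   include_mixed_triplets = FALSE)
  fx <- lrho_fit(dat, spx)
  expect_true(fx$converged)
  expect_false("grp.mixed" %in% names(coef(fx)))
})

test_that("mean functional response is centered at the truth", {
  ## E[f | x] = h(eta) at the true parameter: large-sample kernel mean near
  ## the bivariate-normal grade correlation
  dat <- sim_fixture(n = 600, m = 1, seed = 40)
  expect_equal(ustat_spearman(dat$u[, 1], dat$v[, 1]),
               normal_spearman(0.5), tolerance = 0.06)
})

test_that("solver flags non-convergence instead of erroring", {
  dat <- sim_fixture(n = 30, seed = 50)
  w <- capture_warnings(
    fit <- lrho_fit(dat, visit_spec(), init = c(5, -5, 5),
                    control = default_control(max_iter = 1L)))
  expect_match(w, "did not converge", all = FALSE)
  expect_false(fit$converged)
  expect_error(wald_test(fit, "visit2"), "converge")
})

test_that("degenerate inputs are rejected with clear messages", {
  dat <- sim_fixture(n = 8, seed = 3)
  expect_error(lrho_fit(dat, visit_spec()), "too few subjects")
  dat2 <- sim_fixture(n = 20, m = 2, seed = 3)
  expect_error(lrho_fit(dat2, visit_spec(3)), "visits")
})

test_that("triplet subsampling approximates the full fit", {
  dat <- sim_fixture(n = 60, seed = 55)
  full <- lrho_fit(dat, visit_spec())
  sub <- lrho_fit(dat, visit_spec(), subsample = 8000,
                  control = default_control(subsample_threshold = 40L))
  expect_true(sub$subsampled)
  expect_equal(sub$beta, full$beta, tolerance = 0.15)
  ## same seed, same subsample
  sub2 <- lrho_fit(dat, visit_spec(), subsample = 8000,
                   control = default_control(subsample_threshold = 40L))
  expect_identical(sub$beta, sub2$beta)
})
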