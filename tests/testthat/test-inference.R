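test_that("Wald machinery matches the chi-square oracle", {
  fit <- fake_fit(beta = c(a = 1.2, b = -0.4, c = 0.1),
                  se = c(0.3, 0.2, 0.25))
  ## single coefficient: statistic is the squared z, p from pchisq
  w <- wald_test(fit, "b")
  expect_equal(w$statistic, (-0.4 / 0.2)^2)
  expect_equal(w$z, -2)
  expect_equal(w$p, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_equal(w$p, 2 * stats::pnorm(-2))            # chi2(1) = z^2 identity
  ## null at the estimate: statistic 0, p 1
  w0 <- wald_test(fit, "a", null = 1.2)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  ## joint test with diagonal covariance = sum of squared z
  wj <- wald_test(fit, c("b", "c"))
  expect_equal(wj$statistic, 4 + (0.1 / 0.25)^2)
  expect_equal(wj$df, 2)
  expect_equal(wj$p, stats::pchisq(wj$statistic, 2, lower.tail = FALSE))
  ## numeric contrast row: b - c = 0
  wc <- wald_test(fit, c(0, 1, -1))
  expect_equal(wc$statistic, (-0.5)^2 / (0.2^2 + 0.25^2))
  expect_error(wald_test(fit, rbind(c(0, 1, -1), c(0, 2, -2))),
               "rank deficient")
  expect_error(wald_test(fit, "zzz"), "unknown")
  expect_error(wald_test(fit, c(1, 0)), "columns")
})

test_that("correlation intervals are the mapped linear-predictor intervals", {
  fit <- fake_fit(beta = c(`(Intercept)` = 1.053), se = 0.303, m = 1)
  fit$spec <- lrho_spec(visits = 1)
  fit$rho_profile <- numeric(0)
  ci <- rho_ci(fit, visit = 1)
  zq <- stats::qnorm(0.975)
  expect_equal(unname(ci),
               c(tanh(1.053 / 2),
                 tanh((1.053 - zq * 0.303) / 2),
                 tanh((1.053 + zq * 0.303) / 2)))
  expect_true(all(ci > -1 & ci < 1))
  ## zero SE degenerates to a point
  fit0 <- fake_fit(beta = c(`(Intercept)` = 0.6), se = 0, m = 1)
  fit0$spec <- lrho_spec(visits = 1)
  fit0$rho_profile <- numeric(0)
  ci0 <- rho_ci(fit0, visit = 1)
  expect_equal(unname(ci0[2:3]), rep(tanh(0.3), 2))
  ## huge SE still keeps bounds inside (-1, 1)
  fitb <- fake_fit(beta = c(`(Intercept)` = 0.5), se = 5, m = 1)
  fitb$spec <- lrho_spec(visits = 1)
  fitb$rho_profile <- numeric(0)
  cib <- rho_ci(fitb, visit = 1)
  expect_gt(cib["lower"], -1); expect_lt(cib["upper"], 1)
})

## construct a fake fit whose raw two-sided p for coefficient "target" is p
fit_with_p <- function(p) {
  z <- stats::qnorm(1 - p / 2)
  fake_fit(beta = c(target = z * 0.1, other = 0), se = c(0.1, 0.1))
}

test_that("two-stage screening filters then Bonferroni-corrects", {
  fits <- lapply(c(0.01, 0.15, 0.5), fit_with_p)
  names(fits) <- c("m1", "m2", "m3")
  sc <- screen_features(fits, "target")
  expect_equal(sc$feature, c("m1", "m2", "m3"))
  expect_equal(sc$screened, c(TRUE, TRUE, FALSE))
  expect_equal(sc$adj_p, c(0.02, 0.30, NA), tolerance = 1e-9)
  expect_equal(sc$significant, c(TRUE, FALSE, FALSE))
  ## none retained
  fits2 <- lapply(c(0.5, 0.9), fit_with_p)
  sc2 <- screen_features(fits2, "target")
  expect_false(any(sc2$screened))
  expect_true(all(is.na(sc2$adj_p)))
  ## empty input
  sc0 <- screen_features(list(), "target")
  expect_equal(nrow(sc0), 0L)
  ## adjusted p monotone in raw p within the screened set
  set.seed(1)
  fits3 <- lapply(sort(runif(8, 0, 0.19)), fit_with_p)
  sc3 <- screen_features(fits3, "target")
  expect_false(is.unsorted(sc3$adj_p))
  expect_equal(sc3$adj_p, pmin(1, sc3$raw_p * 8), tolerance = 1e-9)
})

test_that("null features are retained at the stage-1 rate and controlled after", {
  ## p ~ U(0,1) under the null: retained count ~ Binomial(N, 0.2) and the
  ## family-wise error of the Bonferroni step stays at the nominal level
  set.seed(7)
  N <- 2395
  pvals <- runif(N)
  fits <- lapply(pvals, fit_with_p)
  sc <- screen_features(fits, "target")
  k <- sum(sc$screened)
  expect_lt(abs(k - 0.2 * N), 4 * sqrt(N * 0.2 * 0.8))
  ## FWER: P(any significant) = P(min p < 0.05/k) ~ 0.05; a single null draw
  ## should essentially never yield more than a couple of discoveries
  expect_lte(sum(sc$significant), 2L)
})

test_that("features rank by mean absolute correlation with ties broken by label", {
  f1 <- fake_fit(c(x = 0), 1, rho = c(t1 = 0.7, t2 = -0.5, t3 = 0.6))
  f2 <- fake_fit(c(x = 0), 1, rho = c(t1 = 0.4, t2 = 0.4, t3 = -0.4))
  f3 <- fake_fit(c(x = 0), 1, rho = c(t1 = -0.4, t2 = 0.4, t3 = 0.4))
  top <- top_k_by_mean_abs_rho(list(b = f2, a = f1, c = f3), k = 2)
  expect_equal(top$feature, c("a", "b"))
  expect_equal(top$mean_abs_rho, c(0.6, 0.4))
  all3 <- top_k_by_mean_abs_rho(list(b = f2, a = f1, c = f3), k = 10)
  expect_equal(all3$feature, c("a", "b", "c"))     # tie b/c broken by label
})
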