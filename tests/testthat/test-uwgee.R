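test_that("monotone pattern validation accepts, rejects and truncates", {
  u <- matrix(rnorm(9), 3); v <- matrix(rnorm(9), 3)
  ok <- lrho_data(u, v)                                 # all observed
  expect_identical(validate_monotone(ok), ok)
  u2 <- u; u2[1, 3] <- NA                               # (1,1,0): monotone
  d2 <- lrho_data(u2, v)
  expect_silent(validate_monotone(d2))
  u3 <- u; u3[2, 2] <- NA                               # (1,0,1): not monotone
  d3 <- lrho_data(u3, v)
  expect_error(validate_monotone(d3), "non-monotone")
  expect_message(d3t <- validate_monotone(d3, action = "truncate"),
                 "discarded 1")
  expect_equal(d3t$robs[2, ], c(1, 0, 0))
  u4 <- u; u4[3, 1] <- NA                               # missing baseline
  expect_error(validate_monotone(lrho_data(u4, v)), "baseline")
})

test_that("cumulative observation probabilities are products of transitions", {
  des <- lrho_design(n = 80, seed = 61, dropout = list(
    gamma = list(c(1, 0.5, 0.5), c(1, 0.5, 0.5))))
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 61),
                              des$dropout$gamma, seed = 62)
  dm <- fit_dropout(dat)
  expect_equal(dm$pi[, 1], rep(1, 80))
  expect_equal(dm$pi[, 2], dm$p[, 2])
  at3 <- dat$robs[, 2] == 1
  expect_equal(dm$pi[at3, 3], dm$p[at3, 2] * dm$p[at3, 3])
  expect_true(all(is.na(dm$p[!at3, 3])))                # not at risk
  ## monotone decrease where defined
  expect_true(all(dm$pi[at3, 3] <= dm$pi[at3, 2] + 1e-12))
})

test_that("dropout coefficients recover the generating mechanism", {
  des <- lrho_design(n = 800, seed = 70,
                     dropout = list(targets = c(0.85, 0.75)))
  cal <- calibrate_dropout_intercepts(des, seed = 70)
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 71),
                              attr(cal, "gamma"), seed = 72)
  dm <- fit_dropout(dat)
  g2 <- dm$gamma$t2
  expect_equal(unname(g2), c(cal[[1]], 1, 1), tolerance = 0.35)
  g3 <- dm$gamma$t3
  expect_equal(unname(g3[2:3]), c(1, 1), tolerance = 0.4)
})

test_that("MCAR data yield near-zero dropout slopes and a calibrated test", {
  des <- lrho_design(n = 700, seed = 75, dropout = list(
    gamma = list(c(1.7, 0, 0), c(1.1, 0, 0))))
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 75),
                              des$dropout$gamma, seed = 76)
  dm <- fit_dropout(dat)
  expect_lt(max(abs(dm$gamma$t2[2:3])), 0.3)
  ## size of the joint test under MCAR across a few replicates
  rej <- 0L
  for (r in 1:30) {
    d <- simulate_mar_dropout(
      simulate_complete(lrho_design(n = 200), seed = 400 + r),
      des$dropout$gamma, seed = 700 + r)
    p <- mcar_test(fit_dropout(d))$joint$p
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej, 7)   # Binom(30, 0.05): P(X > 7) < 1e-4
})

test_that("MAR dropout is detected with high power", {
  des <- lrho_design(n = 500, seed = 80, dropout = list(targets = c(0.85, 0.75)))
  cal <- calibrate_dropout_intercepts(des, seed = 80)
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 81),
                              attr(cal, "gamma"), seed = 82)
  mt <- mcar_test(fit_dropout(dat))
  expect_lt(mt$joint$p, 0.001)
  expect_equal(mt$joint$df, 4)
})

test_that("no dropout at a transition degenerates gracefully", {
  des <- lrho_design(n = 40, seed = 85, dropout = list(
    gamma = list(c(30, 0, 0), c(30, 0, 0))))     # essentially no dropout
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 85),
                              des$dropout$gamma, seed = 86)
  w <- capture_warnings(dm <- fit_dropout(dat))
  expect_match(w, "no dropout", all = TRUE)
  expect_true(all(is.na(mcar_test(dm)$by_transition$p)))
})

test_that("triplet weights multiply the members' inverse probabilities", {
  des <- lrho_design(n = 100, seed = 90, dropout = list(targets = c(0.85, 0.75)))
  cal <- calibrate_dropout_intercepts(des, seed = 90)
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 91),
                              attr(cal, "gamma"), seed = 92)
  dm <- fit_dropout(dat)
  obs2 <- which(dat$robs[, 2] == 1)[1:3]
  expect_equal(triplet_weights(dm, obs2, 2),
               prod(1 / dm$pi[obs2, 2]))
  drop2 <- which(dat$robs[, 2] == 0)[1]
  expect_identical(triplet_weights(dm, c(obs2[1:2], drop2), 2), 0)
  expect_equal(triplet_weights(dm, obs2, 1), 1)   # baseline: pi = 1
  ## arithmetic example: all pi = 0.85
  dm2 <- dm
  dm2$pi[obs2, 2] <- 0.85
  expect_equal(triplet_weights(dm2, obs2, 2), 0.85^-3, tolerance = 1e-12)
  ## floor triggers a warning
  dm3 <- dm
  dm3$pi[obs2[1], 2] <- 0.001
  expect_warning(w <- triplet_weights(dm3, obs2, 2), "truncated")
  expect_equal(w, (1 / 0.01) * prod(1 / dm$pi[obs2[2:3], 2]))
})

test_that("inverse-probability weighting restores the kernel mean under MAR", {
  ## E[(r/pi) phi] = E[phi] under the true dropout model: weighted kernel
  ## mean on the thinned sample vs the complete-data value, single large
  ## draw, O(n^2) oracle, true cumulative probabilities
  des <- lrho_design(n = 2000, seed = 95, dropout = list(targets = c(0.85, 0.75)))
  cal <- calibrate_dropout_intercepts(des, seed = 95)
  g <- attr(cal, "gamma")
  full <- simulate_complete(des, seed = 96)
  dat <- simulate_mar_dropout(full, g, seed = 97)
  p2 <- stats::plogis(g$t2[1] + full$u[, 1] + full$v[, 1])
  p3 <- stats::plogis(g$t3[1] + full$u[, 2] + full$v[, 2])
  pi_true <- cbind(1, p2, p2 * p3)
  for (t in 2:3) {
    obs <- dat$robs[, t] == 1
    w <- 1 / pi_true[obs, t]
    km_w <- weighted_kernel_mean(dat$u[obs, t], dat$v[obs, t], w)
    km_full <- (ustat_spearman(full$u[, t], full$v[, t]) + 3) / 12
    expect_equal(km_w, km_full, tolerance = 0.012)
    ## unweighted complete-case mean is biased away from it
    km_cc <- weighted_kernel_mean(dat$u[obs, t], dat$v[obs, t], rep(1, sum(obs)))
    expect_gt(abs(km_cc - km_full), abs(km_w - km_full))
  }
})

test_that("weighted fit matches the unweighted fit when nothing is missing", {
  dat <- sim_fixture(n = 40, seed = 99)
  f0 <- lrho_fit(dat, visit_spec(), missing = "none")
  ## force the weighted path on complete data: dropout model has no events
  w <- capture_warnings(fm <- lrho_fit(dat, visit_spec(), missing = "mar"))
  expect_match(w, "no dropout", all = TRUE)
  expect_equal(f0$beta, fm$beta, tolerance = 1e-10)
})

test_that("auto branch picks the weighted analysis only under MAR evidence", {
  des <- lrho_design(n = 300, seed = 101, dropout = list(targets = c(0.85, 0.75)))
  cal <- calibrate_dropout_intercepts(des, seed = 101)
  mar <- simulate_mar_dropout(simulate_complete(des, seed = 102),
                              attr(cal, "gamma"), seed = 103)
  fmar <- lrho_fit(mar, visit_spec(), missing = "auto")
  expect_identical(fmar$missing, "mar")
  expect_true(any(grepl("^gamma\\.", names(coef(fmar)))))
  mcar <- simulate_mar_dropout(simulate_complete(des, seed = 104),
                               list(c(1.7, 0, 0), c(1.1, 0, 0)), seed = 105)
  fmcar <- lrho_fit(mcar, visit_spec(), missing = "auto")
  expect_identical(fmcar$missing, "mcar")
  expect_false(any(grepl("^gamma\\.", names(coef(fmcar)))))
})

test_that("joint sandwich covers the dropout block and stays PSD", {
  des <- lrho_design(n = 120, seed = 110, dropout = list(targets = c(0.85, 0.75)))
  cal <- calibrate_dropout_intercepts(des, seed = 110)
  dat <- simulate_mar_dropout(simulate_complete(des, seed = 111),
                              attr(cal, "gamma"), seed = 112)
  fit <- lrho_fit(dat, visit_spec(), missing = "mar")
  V <- vcov(fit)
  expect_equal(dim(V), c(9L, 9L))    # 3 beta + 2 x 3 gamma
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  ## Wald test on a dropout slope rejects under this strong MAR design
  wt <- wald_test(fit, "gamma.t2.u1")
  expect_lt(wt$p, 0.2)
})

test_that("separated dropout transitions error by default, Firth recovers", {
  set.seed(300)
  n <- 30
  u <- matrix(rnorm(2 * n), n); v <- matrix(rnorm(2 * n), n)
  ## dropout at visit 2 exactly when u1 is below its median: separated
  drop2 <- u[, 1] < stats::median(u[, 1])
  u[drop2, 2] <- NA; v[drop2, 2] <- NA
  dat <- lrho_data(u, v)
  expect_error(fit_dropout(dat), "separation")
  expect_warning(dm <- fit_dropout(dat, on_separation = "firth"), "Firth")
  expect_true(all(is.finite(dm$gamma$t2)))
  expect_gt(dm$gamma$t2[["u1"]], 0)   # observation loads on large u1
})
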