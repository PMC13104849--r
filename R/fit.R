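## Estimating-equation engine shared by the complete-data (UGEE) and
## inverse-probability-weighted (UWGEE) fits. All triplet loops live in C++;
## this file orchestrates Newton iterations, the working-correlation moment
## update, and the sandwich covariance.

#' Solver control parameters
#'
#' @param tol Convergence tolerance on the max-norm of the estimating
#'   function, scaled by the number of triplet combinations.
#' @param max_iter Maximum Newton iterations.
#' @param max_halvings Maximum step halvings per iteration.
#' @param subsample_threshold Subject count above which the `subsample`
#'   argument of [lrho_fit()] is honored.
#' @return A named list.
#' @export
default_control <- function(tol = 1e-9, max_iter = 50L, max_halvings = 10L,
                            subsample_threshold = 400L) {
  list(tol = tol, max_iter = max_iter, max_halvings = max_halvings,
       subsample_threshold = subsample_threshold)
}

## Draw a seeded subsample of distinct i<j<k combinations (0-based matrix).
sample_triplets <- function(n, size, seed) {
  rng <- get_rng_state(); on.exit(restore_rng_state(rng))
  set.seed(seed)
  seen <- character(0)
  out <- matrix(0L, 0L, 3L)
  while (nrow(out) < size) {
    need <- size - nrow(out)
    draw <- t(replicate(need, sort(sample.int(n, 3L))))
    key <- paste(draw[, 1], draw[, 2], draw[, 3])
    new <- !duplicated(key) & !(key %in% seen)
    out <- rbind(out, draw[new, , drop = FALSE])
    seen <- c(seen, key[new])
  }
  out - 1L
}

## Newton solve of the beta block. Returns beta, convergence info, alpha and
## the final pass (with sandwich accumulators).
beta_solve <- function(u, v, wr, xiv, xit, trips, tw, beta0, exchangeable,
                       control, want_sandwich = TRUE) {
  n <- nrow(u)
  ntot <- if (nrow(trips) > 0) nrow(trips) else choose(n, 3)
  alpha <- 0
  pass <- cpp_beta_pass(u, v, wr, xiv, xit, trips, tw, beta0, alpha,
                        TRUE, FALSE)
  beta <- beta0
  unorm <- max(abs(pass$U)) / ntot
  converged <- unorm < control$tol
  iter <- 0L
  while (!converged && iter < control$max_iter) {
    iter <- iter + 1L
    step <- tryCatch(drop(solve(t(pass$B), pass$U)),
                     error = function(e) stop("singular information matrix in UGEE solve"))
    cand <- beta + step
    passc <- cpp_beta_pass(u, v, wr, xiv, xit, trips, tw, cand, alpha,
                           TRUE, FALSE)
    cnorm <- max(abs(passc$U)) / ntot
    if (cnorm > unorm) {
      ## try shortened steps; if none decreases ||U|| keep the full Newton
      ## step (Gauss-Newton often overshoots transiently yet still converges)
      lambda <- 1
      for (hh in seq_len(control$max_halvings)) {
        lambda <- lambda / 2
        cand2 <- beta + lambda * step
        pass2 <- cpp_beta_pass(u, v, wr, xiv, xit, trips, tw, cand2, alpha,
                               TRUE, FALSE)
        cnorm2 <- max(abs(pass2$U)) / ntot
        if (cnorm2 <= unorm) {
          cand <- cand2; passc <- pass2; cnorm <- cnorm2
          break
        }
      }
    }
    beta <- cand
    pass <- passc
    unorm <- cnorm
    if (exchangeable && passc$cn > 0)
      alpha <- min(max(passc$ca / passc$cn, -0.99 / (ncol(u) - 1) + 1e-6), 0.99)
    converged <- unorm < control$tol
  }
  final <- if (want_sandwich)
    cpp_beta_pass(u, v, wr, xiv, xit, trips, tw, beta, alpha, TRUE, TRUE)
  else pass
  list(beta = beta, converged = converged, iterations = iter, unorm = unorm,
       alpha = if (exchangeable) alpha else NULL,
       B = final$B / ntot, W = final$W, ntrip = final$ntrip, ntot = ntot)
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, 0L)
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

## Sandwich covariance from stacked block results.
## blocks: list with elements B (list of square blocks) and W (list of n x q_b
## per-subject score sums); denominators follow the U-statistic sandwich.
sandwich_assemble <- function(Bs, Ws, n, pair_denoms) {
  B <- block_diag(Bs)
  W <- do.call(cbind, Map(function(w, d) w / d, Ws, pair_denoms))
  what <- W                     # n x p matrix of w_i estimates
  Sw <- crossprod(what) / (n - 1)
  Binv <- solve(B)
  Sigma <- 9 * Binv %*% Sw %*% t(Binv)
  Sigma / n
}

## ---- dropout model ------------------------------------------------------

## Firth's bias-reduced logistic regression by modified IRLS: the adjusted
## score X' (y - p + h (1/2 - p)) with hat values h keeps the estimate
## finite under complete or quasi-complete separation.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  g <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% g))
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    h <- rowSums((XW %*% solve(I)) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(U)) < tol) break
    g <- g + drop(solve(I, U))
  }
  g
}

#' Fit the sequential-logistic dropout model
#'
#' For each transition `t = 2..m`, models the probability that a subject
#' observed at `t - 1` remains observed at `t` as a logistic regression on
#' prior outcomes (`logit p_it = gamma_t0 + gamma_t' z_prior`). The
#' coefficients solve the triplet-level estimating equations of the joint
#' weighted system (a standard logistic fit is used as the starting value),
#' so that the joint sandwich covariance is evaluated at an exact zero.
#' Cumulative observation probabilities `pi_it` are products of the fitted
#' transition probabilities.
#'
#' @param data A [lrho_data()] with a monotone missingness pattern.
#' @param lags How many prior visits feed each transition model: `1`
#'   (default; the immediately preceding `(u, v)` pair) or `"all"` (full
#'   observed history).
#' @param on_separation What to do when a transition shows complete or
#'   quasi-complete separation (possible with few dropout events):
#'   `"error"` (default) or `"firth"`, which substitutes Firth's
#'   bias-reduced logistic estimate for that transition (finite under
#'   separation) with a warning.
#' @param tol,max_iter Convergence control for the per-transition solve.
#' @return An object of class `"lrho_dropout"`: per-transition coefficients
#'   `gamma`, transition probabilities `p` (`n x m`, `NA` where undefined),
#'   cumulative probabilities `pi`, model-based covariance per transition,
#'   and bookkeeping for the joint sandwich.
#' @export
fit_dropout <- function(data, lags = 1L,
                        on_separation = c("error", "firth"),
                        tol = 1e-8, max_iter = 25L) {
  on_separation <- match.arg(on_separation)
  data <- validate_monotone(data)
  n <- n_subjects(data); m <- n_visits(data)
  if (m < 2L) stop("dropout model needs at least 2 visits")
  gamma <- vector("list", m - 1L)
  vcov_model <- vector("list", m - 1L)
  predictors <- vector("list", m - 1L)
  p <- matrix(NA_real_, n, m); p[, 1] <- 1
  transitions <- character(0)
  for (t in 2:m) {
    at_risk <- data$robs[, t - 1] == 1
    y <- data$robs[at_risk, t]
    prior <- if (identical(lags, "all")) seq_len(t - 1) else
      seq.int(max(1L, t - as.integer(lags)), t - 1L)
    X <- cbind(`(Intercept)` = 1,
               do.call(cbind, c(
                 stats::setNames(lapply(prior, function(s) data$u[at_risk, s]),
                                 paste0("u", prior)),
                 stats::setNames(lapply(prior, function(s) data$v[at_risk, s]),
                                 paste0("v", prior)))))
    nm <- paste0("t", t)
    predictors[[t - 1L]] <- list(visits = prior, names = colnames(X))
    if (all(y == 1)) {
      warning("no dropout at transition to visit ", t,
              ": p set to 1 with zero variance")
      p[at_risk, t] <- 1
      next
    }
    if (all(y == 0)) {
      warning("all subjects at risk dropped at visit ", t,
              "; that visit contributes nothing")
      p[at_risk, t] <- 0
      next
    }
    gfit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    g0 <- gfit$coefficients
    if (anyNA(g0)) stop("dropout model rank-deficient at transition to visit ", t)
    fit0 <- stats::plogis(drop(X %*% g0))
    separated <- !isTRUE(gfit$converged) || max(abs(g0)) > 15 ||
      (any(fit0 > 1 - 1e-8) && any(fit0 < 1e-8) &&
         all((fit0 > 0.5) == (y == 1)))
    sid <- which(at_risk) - 1L
    if (separated) {
      if (on_separation == "error")
        stop("complete or quasi-complete separation in the dropout model at ",
             "transition to visit ", t, "; reduce predictors (e.g. lags = 1), ",
             "pool transitions, or refit with on_separation = \"firth\"")
      warning("separation at transition to visit ", t,
              "; using Firth bias-reduced logistic estimates")
      gm <- firth_logistic(X, y)
    } else {
      gm <- g0
      for (it in seq_len(max_iter)) {
        pr <- stats::plogis(drop(X %*% gm))
        pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
        pass <- cpp_gamma_pass(X, y - pr, pr * (1 - pr), sid, n, FALSE)
        if (pass$ntrip == 0) break   # fewer than 3 at risk: keep logistic MLE
        if (max(abs(pass$G)) / pass$ntrip < tol) break
        gm <- gm + solve(pass$J, pass$G)
      }
    }
    gamma[[t - 1L]] <- stats::setNames(drop(gm), colnames(X))
    pr <- stats::plogis(drop(X %*% gm))
    p[at_risk, t] <- pr
    a <- pr * (1 - pr)
    info <- crossprod(X * a, X)     # model-based logistic information
    vcov_model[[t - 1L]] <- solve(info)
    transitions <- c(transitions, nm)
  }
  pi <- matrix(NA_real_, n, m); pi[, 1] <- 1
  for (t in 2:m) pi[, t] <- pi[, t - 1] * p[, t]
  structure(list(gamma = stats::setNames(gamma, paste0("t", 2:m)),
                 p = p, pi = pi,
                 vcov_model = stats::setNames(vcov_model, paste0("t", 2:m)),
                 predictors = predictors, lags = lags,
                 transitions = transitions, n = n, m = m,
                 robs = data$robs, data = data),
            class = "lrho_dropout")
}

#' @export
print.lrho_dropout <- function(x, ...) {
  cat("Sequential-logistic dropout model (", x$m, "visits )\n")
  for (t in 2:x$m) {
    g <- x$gamma[[t - 1L]]
    cat("  transition to visit ", t, ": ", sep = "")
    if (is.null(g)) cat("no dropout (p = 1)\n")
    else cat(paste(names(g), sprintf("%.3f", g), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Test the MCAR hypothesis against outcome-dependent dropout
#'
#' Wald tests of zero slopes on prior outcomes in each transition of the
#' dropout model (and jointly across transitions, summing the independent
#' chi-square blocks). A small p-value indicates that missingness depends on
#' observed history (MAR rather than MCAR), in which case the weighted
#' estimating equations should be used.
#'
#' @param dropout A fitted [fit_dropout()] model.
#' @return A list of class `"lrho_mcar"`: per-transition data frame
#'   (`statistic`, `df`, `p`) and the joint test.
#' @export
mcar_test <- function(dropout) {
  stopifnot(inherits(dropout, "lrho_dropout"))
  m <- dropout$m
  stat <- df <- pval <- rep(NA_real_, m - 1L)
  for (t in 2:m) {
    g <- dropout$gamma[[t - 1L]]
    if (is.null(g)) next                       # degenerate: no dropout
    V <- dropout$vcov_model[[t - 1L]]
    sl <- -1L                                  # drop intercept
    gs <- g[sl]; Vs <- V[sl, sl, drop = FALSE]
    stat[t - 1L] <- drop(t(gs) %*% solve(Vs, gs))
    df[t - 1L] <- length(gs)
    pval[t - 1L] <- stats::pchisq(stat[t - 1L], df[t - 1L], lower.tail = FALSE)
  }
  ok <- !is.na(stat)
  joint <- if (any(ok))
    list(statistic = sum(stat[ok]), df = sum(df[ok]),
         p = stats::pchisq(sum(stat[ok]), sum(df[ok]), lower.tail = FALSE))
  else list(statistic = NA_real_, df = NA_real_, p = NA_real_)
  structure(list(
    by_transition = data.frame(transition = paste0("t", 2:m),
                               statistic = stat, df = df, p = pval),
    joint = joint), class = "lrho_mcar")
}

#' @export
print.lrho_mcar <- function(x, ...) {
  cat("MCAR diagnostic (Wald tests of zero outcome slopes in dropout model)\n")
  print(x$by_transition, row.names = FALSE)
  cat(sprintf("joint: chi^2 = %.3f, df = %d, p = %.4g\n",
              x$joint$statistic, as.integer(x$joint$df), x$joint$p))
  invisible(x)
}

#' Inverse-probability weight for one triplet at one visit
#'
#' The product over the triplet's members of `r/pi` (observation indicator
#' over cumulative observation probability). Zero if any member is
#' unobserved at the visit. Probabilities below `floor` are truncated (weight
#' stabilization) with a warning.
#'
#' @param dropout A fitted [fit_dropout()] model.
#' @param triplet Three distinct subject indices.
#' @param t Visit index.
#' @param floor Lower truncation for `pi` (default 0.01).
#' @return A non-negative weight.
#' @export
triplet_weights <- function(dropout, triplet, t, floor = 0.01) {
  stopifnot(inherits(dropout, "lrho_dropout"))
  wr <- subject_weights(dropout, floor)
  prod(wr[triplet, t])
}

## n x m matrix of per-subject r/pi ratios (0 where unobserved).
subject_weights <- function(dropout, floor = 0.01) {
  r <- dropout$robs
  pi <- dropout$pi
  if (any(pi[r == 1] < floor, na.rm = TRUE)) {
    warning("cumulative observation probabilities below ", floor,
            " truncated for weight stabilization")
    pi[pi < floor] <- floor
  }
  wr <- ifelse(r == 1, 1 / pi, 0)
  wr[is.na(wr)] <- 0
  wr
}

## ---- main fit -----------------------------------------------------------

#' Fit the Spearman correlation regression
#'
#' Estimates the coefficients of the correlation regression model by
#' U-statistics based generalized estimating equations over subject triplets
#' (complete data) or by their inverse-probability-weighted extension under
#' monotone missing-at-random dropout, with the corresponding sandwich
#' covariance.
#'
#' `missing` selects the treatment of unobserved visits:
#' \describe{
#'   \item{`"none"`}{require complete data (error otherwise).}
#'   \item{`"mcar"`}{unweighted complete-pair analysis: a triplet contributes
#'     at a visit only if all three members are observed there; valid under
#'     MCAR.}
#'   \item{`"mar"`}{weighted analysis: a sequential-logistic dropout model is
#'     fitted jointly and observed triplets are weighted by the product of
#'     inverse cumulative observation probabilities. The sandwich covariance
#'     is for the stacked parameter (correlation and dropout coefficients).}
#'   \item{`"auto"`}{run the MCAR diagnostic ([mcar_test()]); use `"mcar"`
#'     when its joint p-value exceeds `mcar_level`, else `"mar"`. Complete
#'     data short-circuits to the unweighted fit.}
#' }
#'
#' @param data A [lrho_data()].
#' @param spec A [lrho_spec()].
#' @param missing One of `"auto"`, `"none"`, `"mcar"`, `"mar"`.
#' @param dropout_lags,on_separation Passed to [fit_dropout()] under
#'   `"mar"`/`"auto"`.
#' @param mcar_level Threshold for the `"auto"` branch (default 0.05).
#' @param init Optional starting coefficient vector; by default visit-level
#'   coefficients start at per-visit complete-case classic Spearman estimates
#'   mapped through the link, covariate coefficients at zero.
#' @param se Compute the sandwich covariance (default `TRUE`; skipping it
#'   saves one triplet pass when only point estimates are needed).
#' @param weight_floor Lower truncation for cumulative observation
#'   probabilities in the weights (default 0.01).
#' @param subsample Optional number of triplet combinations to subsample
#'   (seeded; only honored when `n` exceeds `control$subsample_threshold`).
#'   The result is an approximation; all package validation uses full
#'   enumeration.
#' @param subsample_seed Seed for the subsample draw.
#' @param control List from `default_control()`: `tol` (on the max component
#'   of the estimating function scaled by the number of triplets), `max_iter`,
#'   `max_halvings`, `subsample_threshold`.
#' @return An object of class `"lrho_fit"` with components `coefficients`,
#'   `vcov` (joint, including dropout coefficients under `"mar"`), `se`,
#'   `rho` (per-visit correlation profile at the average triplet covariate),
#'   `dropout`, `mcar`, `converged`, `iterations`, `n`, `n_triplets`,
#'   `alpha`, `spec`, `missing`.
#' @references The estimator and its asymptotic theory follow the functional
#'   response model / UGEE framework for between-subject responses; see the
#'   package vignette for the model and formulas.
#' @export
lrho_fit <- function(data, spec,
                     missing = c("auto", "none", "mcar", "mar"),
                     dropout_lags = 1L, on_separation = c("error", "firth"),
                     mcar_level = 0.05,
                     init = NULL, se = TRUE, weight_floor = 0.01,
                     subsample = NULL, subsample_seed = 1L,
                     control = default_control()) {
  missing <- match.arg(missing)
  on_separation <- match.arg(on_separation)
  stopifnot(inherits(data, "lrho_data"), inherits(spec, "lrho_spec"))
  n <- n_subjects(data); m <- n_visits(data)
  if (m != spec$visits) stop("data has ", m, " visits but spec declares ", spec$visits)
  if (n < 10L) stop("too few subjects (need at least 10)")
  complete <- all(data$robs == 1)
  if (missing == "none" && !complete)
    stop("missing data present; choose missing = \"mcar\", \"mar\" or \"auto\"")
  mcar <- NULL
  dropout <- NULL
  if (missing == "auto") {
    if (complete) missing <- "none"
    else {
      dropout <- fit_dropout(data, lags = dropout_lags,
                             on_separation = on_separation)
      mcar <- mcar_test(dropout)
      missing <- if (!is.na(mcar$joint$p) && mcar$joint$p > mcar_level)
        "mcar" else "mar"
    }
  }
  if (missing == "mar" && is.null(dropout)) {
    dropout <- fit_dropout(data, lags = dropout_lags,
                           on_separation = on_separation)
    if (is.null(mcar)) mcar <- mcar_test(dropout)
  }
  wr <- switch(missing,
               none = matrix(1, n, m),
               mcar = data$robs,
               mar = subject_weights(dropout, weight_floor))
  if (missing != "mar") dropout <- NULL

  ## design pieces
  xiv <- visit_part_matrix(spec)
  ptn <- triplet_part_names(spec)
  use_sub <- !is.null(subsample) && n > control$subsample_threshold
  trips <- if (use_sub)
    sample_triplets(n, min(as.integer(subsample), choose(n, 3)), subsample_seed)
  else matrix(0L, 0L, 3L)
  need_trip_rows <- length(ptn) > 0 || !spec$include_mixed_triplets
  if (need_trip_rows && !use_sub) {
    if (choose(n, 3) > 3e6)
      stop("covariate models with n = ", n, " enumerate ", choose(n, 3),
           " triplets; use 'subsample'")
    trips <- t(utils::combn(n, 3L)) - 1L
  }
  cov_df <- data$covariates
  xit <- if (length(ptn))
    triplet_part_matrix(spec, cov_df, t(trips) + 1L)
  else matrix(0, max(nrow(trips), 1L), 0L)
  tw <- if (!spec$include_mixed_triplets && nrow(trips) > 0)
    as.numeric(triplet_keep(spec, cov_df, t(trips) + 1L))
  else numeric(0)

  p <- length(coef_names(spec))
  ## design rank check on a sample of rows
  if (p > 1L) {
    nr <- min(nrow(trips), 500L)
    sample_rows <- if (nr > 0)
      unique(round(seq(1L, nrow(trips), length.out = nr))) else integer(0)
    nr <- length(sample_rows)
    rows <- do.call(rbind, lapply(seq_len(m), function(t) {
      base <- if (ncol(xiv)) matrix(xiv[t, ], 1) else matrix(0, 1, 0)
      if (length(ptn) && nr > 0)
        cbind(base[rep(1, nr), , drop = FALSE],
              xit[sample_rows, , drop = FALSE])
      else base
    }))
    if (qr(rows)$rank < p)
      stop("design matrix is rank deficient; drop redundant builders ",
           "(note categorical_equality already absorbs the intercept)")
  }

  beta0 <- if (!is.null(init)) {
    if (length(init) != p) stop("'init' has wrong length")
    as.numeric(init)
  } else initial_beta(data, spec)

  sol <- beta_solve(data$u, data$v, wr, xiv, xit, trips, tw, beta0,
                    spec$working_correlation == "exchangeable", control,
                    want_sandwich = se)
  if (!sol$converged)
    warning("estimating equations did not converge in ", control$max_iter,
            " iterations (scaled |U| = ", signif(sol$unorm, 3), ")")

  coefs <- stats::setNames(sol$beta, coef_names(spec))
  pair_denom <- if (use_sub) 3 * sol$ntot / n else choose(n - 1, 2)

  Bs <- list(sol$B); Ws <- list(sol$W); denoms <- list(pair_denom)
  cn <- coef_names(spec)
  if (!is.null(dropout)) {
    ntot3 <- choose(n, 3)
    for (t in 2:m) {
      g <- dropout$gamma[[t - 1L]]
      if (is.null(g)) next
      gnm <- paste0("gamma.", names(dropout$gamma)[t - 1L], ".", names(g))
      cn <- c(cn, gnm)
      coefs <- c(coefs, stats::setNames(g, gnm))
      if (!se) next
      at_risk <- dropout$robs[, t - 1] == 1
      Xg <- dropout_design(dropout, t)
      y <- dropout$robs[at_risk, t]
      pr <- dropout$p[at_risk, t]
      pass <- cpp_gamma_pass(Xg, y - pr, pr * (1 - pr),
                             which(at_risk) - 1L, n, TRUE)
      Bs <- c(Bs, list(pass$J / ntot3))
      Ws <- c(Ws, list(pass$W))
      denoms <- c(denoms, list(choose(n - 1, 2)))
    }
  }

  vc <- NULL; ses <- rep(NA_real_, length(coefs))
  if (se && !sol$converged) {
    se <- FALSE                  # sandwich is meaningless off the solution
    warning("covariance not computed for a non-converged fit")
  }
  if (se) {
    vc <- tryCatch(sandwich_assemble(Bs, Ws, n, denoms),
                   error = function(e) stop("sandwich bread matrix is singular"))
    dimnames(vc) <- list(cn, cn)
    ses <- sqrt(pmax(diag(vc), 0))
  }
  names(ses) <- cn

  ## per-visit correlation profile at the average triplet covariate row
  xit_bar <- if (length(ptn)) colMeans(xit[tw_keep_rows(tw, nrow(xit)), ,
                                           drop = FALSE]) else numeric(0)
  rho <- vapply(seq_len(m), function(t) {
    xi <- c(if (ncol(xiv)) xiv[t, ] else numeric(0), xit_bar)
    inv_link_h(sum(sol$beta * xi))
  }, 0)
  names(rho) <- paste0("t", seq_len(m))

  structure(list(coefficients = coefs, vcov = vc, se = ses,
                 beta = stats::setNames(sol$beta, coef_names(spec)),
                 beta_index = seq_len(p),
                 rho = rho, rho_profile = xit_bar,
                 dropout = dropout, mcar = mcar,
                 converged = sol$converged, iterations = sol$iterations,
                 unorm = sol$unorm,
                 n = n, m = m, n_triplets = sol$ntot,
                 alpha = sol$alpha, spec = spec, missing = missing,
                 subsampled = use_sub, call = match.call()),
            class = "lrho_fit")
}

tw_keep_rows <- function(tw, nr) {
  if (!length(tw)) seq_len(nr) else which(tw > 0)
}

## per-transition predictor matrix for the at-risk set (mirrors fit_dropout)
dropout_design <- function(dropout, t) {
  data <- dropout$data
  at_risk <- dropout$robs[, t - 1] == 1
  prior <- dropout$predictors[[t - 1L]]$visits
  cbind(`(Intercept)` = 1,
        do.call(cbind, c(
          stats::setNames(lapply(prior, function(s) data$u[at_risk, s]),
                          paste0("u", prior)),
          stats::setNames(lapply(prior, function(s) data$v[at_risk, s]),
                          paste0("v", prior)))))
}

## starting values: per-visit complete-case classic Spearman through the link
initial_beta <- function(data, spec) {
  m <- n_visits(data)
  g <- vapply(seq_len(m), function(t) {
    ok <- data$robs[, t] == 1
    r <- if (sum(ok) >= 3)
      tryCatch(spearman_classic(data$u[ok, t], data$v[ok, t]),
               error = function(e) 0)
    else 0
    link_g(min(max(r, -0.95), 0.95))
  }, 0)
  p <- length(coef_names(spec))
  beta0 <- numeric(p)
  nmv <- visit_part_names(spec)
  if ("(Intercept)" %in% nmv) beta0[match("(Intercept)", nmv)] <- g[1]
  if (has_visit_indicator(spec))
    for (t in 2:m) beta0[match(paste0("visit", t), nmv)] <- g[t] - g[1]
  if (!spec$intercept) {
    ## equality partition absorbs the intercept: start its columns at g[1]
    eq <- grep("\\.eq[01]$", coef_names(spec))
    beta0[eq] <- g[1]
  }
  beta0
}

#' @export
coef.lrho_fit <- function(object, ...) object$coefficients

#' @export
vcov.lrho_fit <- function(object, ...) object$vcov

#' @export
print.lrho_fit <- function(x, ...) {
  cat("Longitudinal Spearman correlation regression (",
      switch(x$missing, none = "UGEE, complete data",
             mcar = "UGEE, complete-pair", mar = "UWGEE, IPW"), ")\n", sep = "")
  cat("n =", x$n, "subjects,", x$m, "visits,", format(x$n_triplets, big.mark = ","),
      "triplets", if (x$subsampled) "(subsampled)", "\n")
  est <- x$coefficients
  out <- data.frame(estimate = est, se = x$se[names(est)],
                    z = est / x$se[names(est)],
                    p = 2 * stats::pnorm(-abs(est / x$se[names(est)])))
  print(round(out, 4))
  cat("correlation profile:",
      paste(names(x$rho), sprintf("%.3f", x$rho), sep = "=", collapse = " "), "\n")
  if (!x$converged) cat("WARNING: not converged\n")
  invisible(x)
}

#' @export
summary.lrho_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$mcar)) print(object$mcar)
  invisible(object)
}
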