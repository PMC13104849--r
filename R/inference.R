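#' Wald test of a linear hypothesis on the fitted coefficients
#'
#' Tests `H0: L theta = c` using the sandwich covariance:
#' `(L theta - c)' (L V L')^{-1} (L theta - c)` referred to a chi-square
#' distribution with `q = nrow(L)` degrees of freedom. For a single contrast
#' the signed z statistic is also reported.
#'
#' @param fit A converged [lrho_fit()] with a covariance.
#' @param L Contrast specification: a matrix with one row per contrast and
#'   one column per coefficient of `fit`, a single numeric vector (one
#'   contrast), or a character vector of coefficient names (each tested
#'   against its null value).
#' @param null Null value vector `c` (default 0).
#' @return A list of class `"lrho_wald"`: `statistic`, `df`, `p`, and for
#'   single contrasts `z`.
#' @export
#' @examples
#' \dontrun{wald_test(fit, "visit2")            # H0: beta_2 = 0
#' wald_test(fit, c("visit2", "visit3"))}       # joint
wald_test <- function(fit, L, null = 0) {
  stopifnot(inherits(fit, "lrho_fit"))
  if (!fit$converged) stop("fit did not converge; Wald test unavailable")
  if (is.null(fit$vcov)) stop("fit has no covariance (refit with se = TRUE)")
  theta <- fit$coefficients
  p <- length(theta)
  if (is.character(L)) {
    idx <- match(L, names(theta))
    if (anyNA(idx)) stop("unknown coefficient(s): ",
                         paste(L[is.na(idx)], collapse = ", "))
    M <- matrix(0, length(idx), p)
    M[cbind(seq_along(idx), idx)] <- 1
    L <- M
  } else if (is.vector(L)) L <- matrix(L, 1)
  if (ncol(L) != p) stop("contrast matrix has ", ncol(L),
                         " columns; fit has ", p, " coefficients")
  q <- nrow(L)
  if (qr(L)$rank < q) stop("contrast matrix is rank deficient")
  null <- rep_len(null, q)
  d <- drop(L %*% theta) - null
  LVL <- L %*% fit$vcov %*% t(L)
  stat <- tryCatch(drop(t(d) %*% solve(LVL, d)),
                   error = function(e) stop("singular contrast covariance"))
  out <- list(statistic = stat, df = q,
              p = stats::pchisq(stat, q, lower.tail = FALSE),
              z = if (q == 1L) d / sqrt(drop(LVL)) else NULL,
              contrast = L, null = null)
  class(out) <- "lrho_wald"
  out
}

#' @export
print.lrho_wald <- function(x, ...) {
  cat(sprintf("Wald test: chi^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  if (!is.null(x$z)) cat(sprintf("  (z = %.4f, two-sided)\n", x$z))
  invisible(x)
}

#' Correlation-scale confidence interval
#'
#' Delta-method interval for the model-implied Spearman correlation at a
#' design row: the normal interval is formed on the linear-predictor scale
#' (`beta' xi +/- z * SE`) and mapped through the inverse link, so the bounds
#' always lie inside `(-1, 1)`.
#'
#' @param fit A converged [lrho_fit()].
#' @param visit Visit index at which to evaluate the fitted correlation
#'   profile (covariate builders at their average triplet value), or supply
#'   `xi` directly.
#' @param xi Optional explicit design row (length = number of correlation
#'   coefficients).
#' @param level Confidence level (default 0.95).
#' @return Named vector `(rho, lower, upper)`.
#' @export
rho_ci <- function(fit, visit = 1L, xi = NULL, level = 0.95) {
  stopifnot(inherits(fit, "lrho_fit"))
  if (!fit$converged) stop("fit did not converge")
  beta <- fit$beta
  if (is.null(xi)) {
    xiv <- visit_part_matrix(fit$spec)
    xi <- c(if (ncol(xiv)) xiv[visit, ] else numeric(0), fit$rho_profile)
  }
  if (length(xi) != length(beta)) stop("dimension mismatch")
  eta <- sum(beta * xi)
  Vb <- fit$vcov[fit$beta_index, fit$beta_index, drop = FALSE]
  se <- sqrt(max(drop(t(xi) %*% Vb %*% xi), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(rho = inv_link_h(eta),
    lower = inv_link_h(eta - zq * se),
    upper = inv_link_h(eta + zq * se))
}

#' Two-stage feature screening
#'
#' For a collection of per-feature fits of the same model (one metabolite at
#' a time against a common outcome), applies a liberal first-stage filter on
#' the raw p-value of the coefficient of interest, then a Bonferroni
#' correction within the retained set.
#'
#' @param fits Named list of [lrho_fit()] objects (names are feature labels).
#' @param coefficient Name of the coefficient screened on (e.g. `"visit2"`
#'   for a temporal change, or a group-contrast coefficient).
#' @param stage1_threshold First-stage p-value filter (default 0.2).
#' @param alpha Family-wise level for the significance flag (default 0.05).
#' @return A data frame with one row per feature: `feature`, `beta`, `se`,
#'   `raw_p`, `screened`, `adj_p` (`NA` for unscreened features),
#'   `significant`, per-visit correlations `rho_t1..`, and `missing_rate`;
#'   ordered by adjusted p-value then feature label.
#' @export
screen_features <- function(fits, coefficient, stage1_threshold = 0.2,
                            alpha = 0.05) {
  if (!length(fits))
    return(data.frame(feature = character(0), beta = numeric(0),
                      se = numeric(0), raw_p = numeric(0),
                      screened = logical(0), adj_p = numeric(0),
                      significant = logical(0)))
  if (is.null(names(fits))) names(fits) <- paste0("feature", seq_along(fits))
  rows <- lapply(names(fits), function(f) {
    fit <- fits[[f]]
    w <- wald_test(fit, coefficient)
    rho <- fit$rho
    data.frame(feature = f,
               beta = unname(fit$coefficients[coefficient]),
               se = unname(fit$se[coefficient]),
               raw_p = w$p,
               t(stats::setNames(rho, paste0("rho_", names(rho)))),
               missing_rate = 1 - mean(fit_obs_rate(fit)),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$screened <- out$raw_p < stage1_threshold
  k <- sum(out$screened)
  out$adj_p <- ifelse(out$screened, pmin(1, out$raw_p * k), NA_real_)
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  ord <- order(ifelse(is.na(out$adj_p), Inf, out$adj_p), out$feature)
  out <- out[ord, ]
  rownames(out) <- NULL
  lead <- c("feature", "beta", "se", "raw_p", "screened", "adj_p", "significant")
  out[, c(lead, setdiff(names(out), lead))]
}

fit_obs_rate <- function(fit) {
  if (is.null(fit$dropout)) rep(1, fit$m) else colMeans(fit$dropout$robs)
}

#' Rank features by mean absolute fitted correlation
#'
#' Orders features by the mean over visits of the absolute fitted Spearman
#' correlation, descending; ties broken by feature label.
#'
#' @param fits Named list of [lrho_fit()] objects.
#' @param k How many to return (all if `k` exceeds the number of features).
#' @return Data frame `feature`, `mean_abs_rho`, plus per-visit correlations.
#' @export
top_k_by_mean_abs_rho <- function(fits, k) {
  if (is.null(names(fits))) names(fits) <- paste0("feature", seq_along(fits))
  rows <- lapply(names(fits), function(f) {
    rho <- fits[[f]]$rho
    data.frame(feature = f, mean_abs_rho = mean(abs(rho)),
               t(stats::setNames(rho, paste0("rho_", names(rho)))),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_abs_rho, out$feature), ]
  rownames(out) <- NULL
  utils::head(out, min(as.integer(k), nrow(out)))
}
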