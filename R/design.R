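#' Fisher z-type link for correlations
#'
#' `g(rho) = log((1 + rho) / (1 - rho))` maps a correlation in `(-1, 1)` to
#' the real line; its inverse `h(eta) = (exp(eta) - 1) / (exp(eta) + 1)`
#' (equal to `tanh(eta / 2)`) maps a linear predictor back to the correlation
#' scale. The regression model is linear on the `g` scale.
#'
#' @param rho Correlation(s), strictly inside `(-1, 1)`.
#' @param eta Linear predictor(s), any finite real.
#' @return Transformed value(s).
#' @export
#' @examples
#' link_g(0.483)       # about 1.053
#' inv_link_h(1.053)   # about 0.483
link_g <- function(rho) {
  if (!is.numeric(rho) || anyNA(rho) || any(abs(rho) >= 1))
    stop("boundary correlation: 'rho' must lie strictly inside (-1, 1)")
  log((1 + rho) / (1 - rho))
}

#' @rdname link_g
#' @export
inv_link_h <- function(eta) {
  if (!is.numeric(eta) || anyNA(eta) || any(!is.finite(eta)))
    stop("'eta' must be finite")
  tanh(eta / 2)  # = (exp(eta) - 1)/(exp(eta) + 1), overflow-free
}

## derivative dh/deta = (1 - h^2)/2
dinv_link_h <- function(eta) {
  h <- tanh(eta / 2)
  (1 - h * h) / 2
}

builder_kinds <- c("continuous_mean", "continuous_median",
                   "categorical_equality", "group_contrast",
                   "visit_indicator")

#' Specify a correlation regression model
#'
#' Defines the linear predictor for the triplet-level functional response:
#' which triplet-level covariate summaries enter, whether visit indicators are
#' included, and the working correlation among the repeated responses.
#'
#' Builder kinds (each operates on one subject-level covariate column, turned
#' into a triplet-level design value):
#' \describe{
#'   \item{`visit_indicator`}{indicators `I(t = s)` for visits `s = 2..m`,
#'     so the intercept is the baseline-visit effect and later coefficients
#'     are changes from baseline.}
#'   \item{`continuous_mean` / `continuous_median`}{mean or median of the
#'     three subjects' covariate values.}
#'   \item{`categorical_equality`}{for a binary covariate, the partition
#'     indicators (all three subjects 0; all three 1; mixed). Replaces the
#'     intercept, since the three indicators sum to one.}
#'   \item{`group_contrast`}{the same partition re-parameterized as
#'     intercept + `I(all 1)` + `I(mixed)`, so equality of the two
#'     within-group correlations is a single-coefficient test.}
#' }
#'
#' @param visits Number of assessment visits `m >= 1`.
#' @param builders A list of builders, each a `list(name=, kind=, column=)`
#'   where `column` names a subject-level covariate column (not needed for
#'   `visit_indicator`). A bare character `"visit_indicator"` entry is also
#'   accepted. May be empty: intercept-only model.
#' @param include_mixed_triplets If `FALSE`, triplets whose members span both
#'   levels of a `categorical_equality`/`group_contrast` covariate are dropped
#'   from the estimating equations and the mixed-indicator column is omitted.
#' @param working_correlation Working correlation among a triplet's repeated
#'   responses: `"independence"` (default) or `"exchangeable"`. Affects
#'   efficiency, not consistency.
#' @return An object of class `"lrho_spec"`.
#' @export
#' @examples
#' lrho_spec(visits = 3, builders = list("visit_indicator"))
lrho_spec <- function(visits = 1L,
                      builders = list(),
                      include_mixed_triplets = TRUE,
                      working_correlation = c("independence", "exchangeable")) {
  working_correlation <- match.arg(working_correlation)
  visits <- as.integer(visits)
  if (is.na(visits) || visits < 1L) stop("'visits' must be a positive integer")
  if (is.character(builders)) builders <- as.list(builders)
  builders <- lapply(builders, function(b) {
    if (is.character(b) && length(b) == 1L) b <- list(kind = b)
    if (is.null(b$kind) || !b$kind %in% builder_kinds)
      stop("unknown builder kind; must be one of: ",
           paste(builder_kinds, collapse = ", "))
    if (b$kind != "visit_indicator" && is.null(b$column))
      stop("builder of kind '", b$kind, "' needs a 'column'")
    if (is.null(b$name))
      b$name <- if (b$kind == "visit_indicator") "visit" else b$column
    b
  })
  kinds <- vapply(builders, `[[`, "", "kind")
  if (sum(kinds == "visit_indicator") > 1L)
    stop("at most one visit_indicator builder")
  if (any(kinds == "visit_indicator") && visits < 2L)
    stop("visit_indicator requires at least 2 visits")
  n_eq <- sum(kinds == "categorical_equality")
  if (n_eq > 1L)
    stop("at most one categorical_equality builder (its indicators partition)")
  structure(
    list(visits = visits,
         builders = builders,
         include_mixed_triplets = isTRUE(include_mixed_triplets),
         working_correlation = working_correlation,
         intercept = n_eq == 0L),
    class = "lrho_spec")
}

#' @export
print.lrho_spec <- function(x, ...) {
  cat("Correlation regression model specification\n")
  cat("  visits:", x$visits, "\n")
  cat("  intercept:", x$intercept, "\n")
  for (b in x$builders)
    cat("  builder:", b$name, "<", b$kind, ">",
        if (!is.null(b$column)) paste0("on '", b$column, "'") else "", "\n")
  cat("  mixed-group triplets:",
      if (x$include_mixed_triplets) "included" else "excluded", "\n")
  cat("  working correlation:", x$working_correlation, "\n")
  invisible(x)
}

## ---- internal design assembly ------------------------------------------

## Names of the visit-level part of the design (intercept + visit dummies).
visit_part_names <- function(spec) {
  nm <- character(0)
  if (spec$intercept) nm <- "(Intercept)"
  if (has_visit_indicator(spec))
    nm <- c(nm, paste0("visit", 2:spec$visits))
  nm
}

has_visit_indicator <- function(spec) {
  any(vapply(spec$builders, `[[`, "", "kind") == "visit_indicator")
}

## m x p_vis matrix: row t is the visit-level design at visit t.
visit_part_matrix <- function(spec) {
  m <- spec$visits
  cols <- list()
  if (spec$intercept) cols$`(Intercept)` <- rep(1, m)
  if (has_visit_indicator(spec))
    for (s in 2:m) cols[[paste0("visit", s)]] <- as.numeric(seq_len(m) == s)
  if (!length(cols)) return(matrix(0, m, 0))
  do.call(cbind, cols)
}

## Column names of the triplet-level builder part.
triplet_part_names <- function(spec) {
  out <- character(0)
  for (b in spec$builders) {
    out <- c(out, switch(b$kind,
      visit_indicator = character(0),
      continuous_mean = paste0(b$name, ".mean"),
      continuous_median = paste0(b$name, ".median"),
      categorical_equality =
        paste0(b$name, c(".eq0", ".eq1",
                         if (spec$include_mixed_triplets) ".mixed")),
      group_contrast =
        paste0(b$name, c(".diff", if (spec$include_mixed_triplets) ".mixed"))
    ))
  }
  out
}

coef_names <- function(spec) c(visit_part_names(spec), triplet_part_names(spec))

check_binary <- function(x, column) {
  ux <- unique(x[!is.na(x)])
  if (!all(ux %in% c(0, 1)))
    stop("unsupported: covariate '", column,
         "' must be binary 0/1 (categorical covariates with >2 levels are not supported)")
}

## Builder part for one triplet (length = length(triplet_part_names)).
## covariates: data.frame/matrix with one row per subject.
triplet_part_row <- function(spec, covariates, idx) {
  out <- numeric(0)
  for (b in spec$builders) {
    if (b$kind == "visit_indicator") next
    x <- covariates[[b$column]]
    if (is.null(x)) stop("covariate column '", b$column, "' not found")
    x3 <- x[idx]
    if (anyNA(x3)) stop("missing covariate '", b$column, "' in triplet")
    val <- switch(b$kind,
      continuous_mean = mean(x3),
      continuous_median = stats::median(x3),
      categorical_equality = {
        check_binary(x, b$column)
        c(as.numeric(all(x3 == 0)), as.numeric(all(x3 == 1)),
          if (spec$include_mixed_triplets)
            as.numeric(any(x3 == 0) && any(x3 == 1)))
      },
      group_contrast = {
        check_binary(x, b$column)
        c(as.numeric(all(x3 == 1)),
          if (spec$include_mixed_triplets)
            as.numeric(any(x3 == 0) && any(x3 == 1)))
      })
    out <- c(out, val)
  }
  out
}

#' Triplet-level design row
#'
#' Builds the full covariate vector `xi(x_i, t)` entering the linear predictor
#' for one subject triplet at one visit: intercept and visit indicators plus
#' the triplet-level summaries defined by the model's builders.
#'
#' @param spec A [lrho_spec()].
#' @param covariates Data frame of subject-level covariates (one row per
#'   subject, in subject order).
#' @param triplet Integer vector of three distinct subject indices.
#' @param t Visit index in `1..visits`.
#' @return Named numeric vector of length equal to the model dimension.
#' @export
build_triplet_covariates <- function(spec, covariates, triplet, t) {
  stopifnot(inherits(spec, "lrho_spec"))
  triplet <- as.integer(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet))
    stop("'triplet' must be three distinct subject indices")
  t <- as.integer(t)
  if (t < 1L || t > spec$visits) stop("visit out of range")
  vis <- visit_part_matrix(spec)
  row <- c(if (ncol(vis)) vis[t, ] else numeric(0),
           triplet_part_row(spec, covariates, triplet))
  stats::setNames(row, coef_names(spec))
}

## Full triplet-level builder matrix, combinations in lexicographic i<j<k
## order (same order the C++ enumerator uses). trips: 3 x T integer matrix.
triplet_part_matrix <- function(spec, covariates, trips) {
  nm <- triplet_part_names(spec)
  if (!length(nm)) return(matrix(0, ncol(trips), 0))
  out <- matrix(0, ncol(trips), length(nm))
  for (r in seq_len(ncol(trips)))
    out[r, ] <- triplet_part_row(spec, covariates, trips[, r])
  colnames(out) <- nm
  out
}

## Should this triplet be kept? FALSE only when mixed triplets are excluded
## and some categorical builder is mixed across the triplet.
triplet_keep <- function(spec, covariates, trips) {
  keep <- rep(TRUE, ncol(trips))
  if (spec$include_mixed_triplets) return(keep)
  for (b in spec$builders) {
    if (!b$kind %in% c("categorical_equality", "group_contrast")) next
    x <- covariates[[b$column]]
    for (r in seq_len(ncol(trips))) {
      x3 <- x[trips[, r]]
      if (any(x3 == 0) && any(x3 == 1)) keep[r] <- FALSE
    }
  }
  keep
}

#' Model-implied Spearman correlation for a design row
#'
#' Maps `beta' xi` through the inverse link `h`.
#'
#' @param beta Coefficient vector.
#' @param xi Design row (same length as `beta`), e.g. from
#'   [build_triplet_covariates()].
#' @return Correlation in `(-1, 1)`.
#' @export
predict_rho <- function(beta, xi) {
  if (length(beta) != length(xi))
    stop("dimension mismatch between 'beta' and 'xi'")
  inv_link_h(sum(beta * xi))
}
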