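#' Longitudinal bivariate dataset
#'
#' Container for paired longitudinal outcomes: for each of `n` subjects and
#' each of `m` visits, a bivariate pair `(u, v)` (e.g. a metabolite level and
#' an anxiety score), optional subject-level covariates, and the derived
#' observation indicators. A visit with `NA` in either component is treated as
#' unobserved as a pair: the concordance kernel needs both outcomes.
#'
#' @param u,v Numeric `n x m` matrices (subjects by visits).
#' @param covariates Optional data frame of subject-level covariates with `n`
#'   rows, in subject order.
#' @param subjects Optional subject identifiers (length `n`).
#' @param visit_labels Optional visit labels (length `m`).
#' @return An object of class `"lrho_data"` with elements `u`, `v`, `robs`
#'   (0/1 observation matrix), `covariates`, `subjects`, `visit_labels`.
#' @export
lrho_data <- function(u, v, covariates = NULL, subjects = NULL,
                      visit_labels = NULL) {
  u <- as.matrix(u); v <- as.matrix(v)
  storage.mode(u) <- "double"; storage.mode(v) <- "double"
  if (!identical(dim(u), dim(v))) stop("'u' and 'v' must have the same dimensions")
  n <- nrow(u); m <- ncol(u)
  robs <- matrix(as.numeric(is.finite(u) & is.finite(v)), n, m)
  u[robs == 0] <- NA_real_
  v[robs == 0] <- NA_real_
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("'covariates' must have one row per subject")
  }
  if (is.null(subjects)) subjects <- seq_len(n)
  if (length(subjects) != n) stop("'subjects' must have length n")
  if (is.null(visit_labels)) visit_labels <- seq_len(m)
  structure(list(u = u, v = v, robs = robs, covariates = covariates,
                 subjects = subjects, visit_labels = visit_labels),
            class = "lrho_data")
}

n_subjects <- function(data) nrow(data$u)
n_visits <- function(data) ncol(data$u)

#' @export
print.lrho_data <- function(x, ...) {
  n <- n_subjects(x); m <- n_visits(x)
  cat("Longitudinal bivariate dataset:", n, "subjects x", m, "visits\n")
  obs <- colMeans(x$robs)
  cat("  observed proportion by visit:",
      paste(sprintf("%.3f", obs), collapse = " "), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  mono <- is_monotone(x$robs)
  cat("  missingness pattern:",
      if (all(x$robs == 1)) "complete" else if (mono) "monotone" else "non-monotone",
      "\n")
  invisible(x)
}

is_monotone <- function(robs) {
  m <- ncol(robs)
  if (m < 2L) return(TRUE)
  for (t in 2:m) if (any(robs[, t] == 1 & robs[, t - 1] == 0)) return(FALSE)
  TRUE
}

#' Validate (or enforce) a monotone missingness pattern
#'
#' The weighted estimating equations assume a monotone missing data pattern:
#' baseline fully observed and no visit observed after a missing one. This
#' checks the pattern and either rejects or truncates non-monotone subjects
#' at their first missing visit.
#'
#' @param data A [lrho_data()].
#' @param action `"error"` (default) or `"truncate"` (drop observations after
#'   a subject's first missing visit, reporting how many were discarded).
#' @return The validated (possibly truncated) dataset.
#' @export
validate_monotone <- function(data, action = c("error", "truncate")) {
  action <- match.arg(action)
  stopifnot(inherits(data, "lrho_data"))
  if (any(data$robs[, 1] == 0))
    stop("baseline must be complete: ", sum(data$robs[, 1] == 0),
         " subject(s) unobserved at visit 1")
  if (is_monotone(data$robs)) return(data)
  if (action == "error")
    stop("non-monotone missingness pattern; use action = \"truncate\" to monotonize")
  m <- n_visits(data)
  truncated <- 0L
  for (i in seq_len(n_subjects(data))) {
    first0 <- match(0, data$robs[i, ])
    if (!is.na(first0) && first0 < m) {
      later <- (first0 + 1):m
      truncated <- truncated + sum(data$robs[i, later] == 1)
      data$robs[i, later] <- 0
      data$u[i, later] <- NA_real_
      data$v[i, later] <- NA_real_
    }
  }
  message("monotonized: discarded ", truncated,
          " observation(s) occurring after a missing visit")
  data
}

#' Read a long-format longitudinal dataset
#'
#' Reads a CSV/TSV file with one row per subject-visit and assembles a
#' [lrho_data()]. Visits may carry arbitrary sortable labels; they are mapped
#' to `1..m` in sorted order (the mapping is kept in `visit_labels`). Subjects
#' missing the baseline visit are dropped with a message. `NA` in either
#' outcome marks the whole pair unobserved at that visit.
#'
#' @param path Path to a delimited text file with a header.
#' @param columns Named list mapping roles to column names:
#'   `id`, `visit`, `u`, `v`, and optionally `covariates` (character vector).
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @return A [lrho_data()].
#' @export
read_long_csv <- function(path,
                          columns = list(id = "id", visit = "visit",
                                         u = "u", v = "v", covariates = NULL),
                          sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(columns$id, columns$visit, columns$u, columns$v, columns$covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cl in c(columns$u, columns$v))
    if (!is.numeric(df[[cl]])) stop("outcome column '", cl, "' must be numeric")
  id <- df[[columns$id]]
  visit <- df[[columns$visit]]
  if (anyDuplicated(paste(id, visit, sep = "\r")))
    stop("duplicate (id, visit) rows")
  vlab <- sort(unique(visit))
  m <- length(vlab)
  ids <- unique(id)
  n <- length(ids)
  u <- matrix(NA_real_, n, m); v <- matrix(NA_real_, n, m)
  ri <- match(id, ids); ci <- match(visit, vlab)
  u[cbind(ri, ci)] <- df[[columns$u]]
  v[cbind(ri, ci)] <- df[[columns$v]]
  covs <- NULL
  if (length(columns$covariates)) {
    covs <- unique(df[c(columns$id, columns$covariates)])
    if (nrow(covs) != n)
      stop("covariates must be constant within subject")
    covs <- covs[match(ids, covs[[columns$id]]), columns$covariates, drop = FALSE]
    rownames(covs) <- NULL
  }
  keep <- is.finite(u[, 1]) & is.finite(v[, 1])
  if (!all(keep)) {
    message("dropped ", sum(!keep), " subject(s) without a complete baseline pair")
    u <- u[keep, , drop = FALSE]; v <- v[keep, , drop = FALSE]
    ids <- ids[keep]
    if (!is.null(covs)) covs <- covs[keep, , drop = FALSE]
  }
  lrho_data(u, v, covariates = covs, subjects = ids, visit_labels = vlab)
}

#' Write / read a fitted model as JSON
#'
#' Serializes the coefficient vector, joint sandwich covariance, per-visit
#' correlation profile, dropout model and convergence diagnostics to a
#' versioned JSON file; `read_fit` restores the numeric content (full
#' precision round trip of coefficients and covariance).
#'
#' @param fit A fitted model from [lrho_fit()].
#' @param path Output path.
#' @return `write_fit` invisibly returns `path`; `read_fit` returns a list.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "lrho_fit"))
  obj <- list(
    schema = "lrho-fit/1",
    coefficients = as.list(coef(fit)),
    vcov = unname(fit$vcov), vcov_names = colnames(fit$vcov),
    rho = fit$rho,
    se = as.list(fit$se),
    missing = fit$missing,
    converged = fit$converged, iterations = fit$iterations,
    n_subjects = fit$n, n_triplets = fit$n_triplets,
    working_alpha = fit$alpha,
    dropout = if (!is.null(fit$dropout))
      list(gamma = lapply(fit$dropout$gamma, as.list),
           transitions = fit$dropout$transitions),
    mcar = if (!is.null(fit$mcar))
      list(statistic = fit$mcar$joint$statistic, df = fit$mcar$joint$df,
           p = fit$mcar$joint$p)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "lrho-fit/1"))
    stop("unrecognized fit schema")
  obj$coefficients <- unlist(obj$coefficients)
  obj$vcov <- matrix(unlist(obj$vcov), length(obj$coefficients),
                     dimnames = list(obj$vcov_names, obj$vcov_names))
  obj
}

#' Write a feature-screening table as TSV
#'
#' Fixed column order: `feature`, `beta`, `se`, `raw_p`, `screened`, `adj_p`,
#' `significant`, then any additional columns (per-visit correlations,
#' missing rates). An empty result writes the header only.
#'
#' @param table A data frame from [screen_features()].
#' @param path Output path.
#' @export
write_screen <- function(table, path) {
  lead <- c("feature", "beta", "se", "raw_p", "screened", "adj_p", "significant")
  cols <- c(intersect(lead, names(table)), setdiff(names(table), lead))
  utils::write.table(table[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
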