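#' Classic rank-based Spearman correlation
#'
#' Pearson correlation of the rank vectors of `u` and `v`, with average ranks
#' for ties. This is the textbook sample estimator; within the package it
#' serves as the oracle against which the triplet U-statistic estimator
#' ([ustat_spearman()]) is checked, and as the initializer for the
#' estimating-equation solver.
#'
#' @param u,v Numeric vectors of equal length (at least 3), no missing values.
#' @return A single correlation in `[-1, 1]`.
#' @seealso [ustat_spearman()], [triplet_kernel()]
#' @export
#' @examples
#' spearman_classic(1:5, c(2, 1, 4, 3, 5))
spearman_classic <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) stop("'u' and 'v' must have equal length")
  if (anyNA(u) || anyNA(v)) stop("missing values not allowed")
  if (length(u) < 3L) stop("insufficient data: need at least 3 pairs")
  p <- rank(u)
  q <- rank(v)
  if (stats::var(p) == 0 || stats::var(q) == 0)
    stop("degenerate: zero rank variance (all values tied)")
  stats::cor(p, q)
}

#' Three-subject concordance kernel
#'
#' The indicator kernel `I(u_j < u_i) * I(v_k < v_i)` over a triplet of
#' bivariate observations. Its expectation `E[phi]` determines the population
#' (grade) Spearman correlation through `rho = 12 E[phi] - 3`. Inequalities are
#' strict: ties contribute 0 (continuous outcomes assumed).
#'
#' @param z_i,z_j,z_k Numeric vectors of length 2, `(u, v)` for one subject
#'   each; all components must be observed.
#' @return 0 or 1.
#' @export
#' @examples
#' triplet_kernel(c(2, 2), c(1, 0), c(0, 1)) # 1
#' triplet_kernel(c(1, 1), c(1, 0), c(0, 0)) # 0: tie in u
triplet_kernel <- function(z_i, z_j, z_k) {
  for (z in list(z_i, z_j, z_k)) {
    if (length(z) != 2L || anyNA(z) || !all(is.finite(z)))
      stop("each argument must be a fully observed (u, v) pair")
  }
  as.numeric(z_j[1L] < z_i[1L] && z_k[2L] < z_i[2L])
}

#' Map a kernel mean to the Spearman correlation scale
#'
#' `rho = 12 * mean_phi - 3`. A kernel mean of 1/4 corresponds to
#' independence (rho = 0); 1/3 and 1/6 to perfect concordance and
#' discordance.
#'
#' @param mean_phi Mean of the concordance kernel, in `[0, 1]`.
#' @return Correlation on `[-1, 1]` scale (values of `mean_phi` outside
#'   `[1/6, 1/3]` can map outside; they cannot arise from data).
#' @export
rho_from_kernel_mean <- function(mean_phi) {
  if (!is.numeric(mean_phi) || anyNA(mean_phi) ||
      any(mean_phi < 0) || any(mean_phi > 1))
    stop("'mean_phi' must lie in [0, 1]")
  12 * mean_phi - 3
}

## Kernel mean over all ordered triples of distinct indices, via rank sums:
## sum over ordered (i,j,k), j != i, k != i, k != j of I(u_j<u_i) I(v_k<v_i)
##   = sum_i a_i * b_i - c_i,
## a_i = #{j != i: u_j < u_i}, b_i likewise for v, c_i = #{j: u_j<u_i, v_j<v_i}
## (the subtraction removes j == k). Tie-free data assumed.
kernel_mean_ordered <- function(u, v) {
  n <- length(u)
  a <- rank(u, ties.method = "min") - 1
  b <- rank(v, ties.method = "min") - 1
  o <- order(u)
  uu <- u[o]; vv <- v[o]
  cc <- numeric(n)
  for (i in seq_len(n)) {          # O(n^2); n <= a few thousand in practice
    cc[o[i]] <- if (i > 1L)
      sum(vv[seq_len(i - 1L)] < vv[i] & uu[seq_len(i - 1L)] < uu[i])
    else 0
  }
  sum(a * b - cc) / (n * (n - 1) * (n - 2))
}

#' U-statistic Spearman correlation
#'
#' Estimates Spearman's rho as `12 * mean(phi) - 3`, with the concordance
#' kernel averaged over all ordered triples of distinct subjects (equivalently,
#' the kernel symmetrized over the 6 orderings of each combination). This is
#' the estimator targeted by the estimating-equation machinery; on tie-free
#' data it agrees with [spearman_classic()] up to `O(1/n)`.
#'
#' @param u,v Numeric vectors of equal length `n >= 3`, no missing values.
#' @param ties How to handle tied values: `"warn"` (default) applies the
#'   strict-inequality kernel and warns, `"jitter"` breaks ties with a
#'   deterministic, seeded perturbation of magnitude `1e-9` times the data
#'   scale, `"error"` stops.
#' @return Estimated correlation.
#' @export
#' @examples
#' set.seed(1)
#' u <- rnorm(30)
#' ustat_spearman(u, u^3) # exactly 1 up to triple-enumeration discreteness
ustat_spearman <- function(u, v, ties = c("warn", "jitter", "error")) {
  ties <- match.arg(ties)
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) stop("'u' and 'v' must have equal length")
  if (anyNA(u) || anyNA(v)) stop("missing values not allowed")
  n <- length(u)
  if (n < 3L) stop("insufficient data: need at least 3 pairs")
  if (anyDuplicated(u) || anyDuplicated(v)) {
    if (ties == "error") stop("tied values present")
    if (ties == "jitter") {
      u <- break_ties(u)
      v <- break_ties(v)
    } else {
      warning("tied values present; strict-inequality kernel treats ties as discordant")
    }
  }
  rho_from_kernel_mean(kernel_mean_ordered(u, v))
}

## Deterministic tie-breaking: rank-ordered epsilon perturbation, seeded so the
## same input always yields the same jitter. Magnitude 1e-9 * data scale.
break_ties <- function(x) {
  if (!anyDuplicated(x)) return(x)
  scale <- max(diff(range(x)), abs(x), 1e-8)
  rng <- get_rng_state()
  on.exit(restore_rng_state(rng))
  set.seed(2026L)
  x + sample.int(length(x)) * (1e-9 * scale / length(x))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
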