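## Brute-force oracle: concordance-kernel mean over all ordered triples of
## distinct indices, by literal enumeration. Independent of the package's
## rank-sum and C++ implementations.
brute_force_ustat <- function(u, v) {
  n <- length(u)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    s <- s + (u[j] < u[i]) * (v[k] < v[i])
  }
  12 * s / (n * (n - 1) * (n - 2)) - 3
}

## Weighted ordered-triple kernel mean with per-subject product weights,
## via O(n^2) sums (oracle for the inverse-probability weighting identity).
weighted_kernel_mean <- function(u, v, w) {
  n <- length(u)
  A <- B <- C <- numeric(n)
  for (i in seq_len(n)) {
    lu <- u < u[i]; lv <- v < v[i]
    A[i] <- sum(w[lu]) - 0
    B[i] <- sum(w[lv])
    C[i] <- sum(w[lu & lv]^2)
  }
  num <- sum(w * (A * B - C))
  s1 <- sum(w); s2 <- sum(w^2); s3 <- sum(w^3)
  den <- s1^3 - 3 * s1 * s2 + 2 * s3
  num / den
}

## A small complete-data fixture with known dependence.
sim_fixture <- function(n = 40, m = 3, seed = 1, delta = 0.5, phi = 0.25) {
  simulate_complete(lrho_design(n = n, m = m, delta = delta, phi = phi),
                    seed = seed)
}

visit_spec <- function(m = 3, ...) {
  lrho_spec(visits = m, builders = list("visit_indicator"), ...)
}

## A stand-in fit object with prescribed coefficient/SE pairs, for testing
## inference arithmetic independently of the solver.
fake_fit <- function(beta, se, rho = NULL, m = 3) {
  p <- length(beta)
  if (is.null(names(beta))) names(beta) <- paste0("b", seq_len(p))
  V <- diag(se^2, p)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, beta = beta, vcov = V,
                 se = stats::setNames(se, names(beta)),
                 beta_index = seq_len(p),
                 rho = rho %||% stats::setNames(rep(0.3, m), paste0("t", 1:m)),
                 m = m, converged = TRUE, dropout = NULL),
            class = "lrho_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
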