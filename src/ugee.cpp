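// Triplet-kernel estimating equations for longitudinal Spearman regression.
//
// One pass over subject triplets computes, at the current beta:
//   U  = sum_i D_i V_i^-1 Delta_i S_i          (estimating function)
//   B  = sum_i D_i Delta_i V_i^-1 D_i^T        (bread; Newton matrix = B^T)
//   W  = per-subject sums of D V^-1 Delta S    (for the sandwich meat)
// where i runs over combinations {i<j<k}, S_it = f_it - h_it with
// f_it = 12*phi - 3, phi the (optionally permutation-symmetrized)
// concordance kernel, and Delta_i holds the triplet inverse-probability
// weights (all 1 for complete data). Working variance A = (h+3)(9-h);
// working correlation independence (alpha = 0) or exchangeable.
//
// When the design has no triplet-level covariate columns (pt == 0) the mean
// model is constant across triplets at each visit, so U and B reduce to
// per-visit sums of the weighted residuals; that fast path makes the
// n-choose-3 enumeration cheap enough for Monte Carlo use.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double kernel_phi(double ui, double uj, double uk,
                                double vi, double vj, double vk,
                                bool sym) {
  if (!sym) return (uj < ui && vk < vi) ? 1.0 : 0.0;
  int s = 0;
  s += (uj < ui && vk < vi);
  s += (uk < ui && vj < vi);
  s += (ui < uj && vk < vj);
  s += (uk < uj && vi < vj);
  s += (ui < uk && vj < vk);
  s += (uj < uk && vi < vk);
  return s / 6.0;
}

// [[Rcpp::export]]
List cpp_beta_pass(const arma::mat& u, const arma::mat& v, const arma::mat& wr,
                   const arma::mat& xiv, const arma::mat& xit,
                   const arma::imat& trips, const arma::vec& tw,
                   const arma::vec& beta, double alpha,
                   bool symmetrize, bool sandwich) {
  const int n = u.n_rows, m = u.n_cols;
  const int pv = xiv.n_cols, pt = xit.n_cols, p = pv + pt;
  const bool exch = (alpha != 0.0);
  const bool have_tw = tw.n_elem > 0;
  const bool have_trips = trips.n_rows > 0;

  double rdiag = 1.0, roff = 0.0;           // exchangeable R^-1 entries
  if (exch) {
    double a1 = alpha / (1.0 + (m - 1) * alpha);
    rdiag = (1.0 - a1 * 1.0) / (1.0 - alpha);
    roff = -a1 / (1.0 - alpha);
  }

  arma::vec U(p, arma::fill::zeros);
  arma::mat B(p, p, arma::fill::zeros);
  arma::mat W(sandwich ? n : 1, sandwich ? p : 1, arma::fill::zeros);
  double ca = 0.0, cn = 0.0, Tn = 0.0;

  std::vector<double> S(m), w3(m), q(m), Wbuf(p);

  if (pt == 0) {
    // ---- fast path: mean model constant across triplets ----
    std::vector<double> h(m), dd(m), A(m), rA(m);
    arma::mat xim(p, m);
    for (int t = 0; t < m; ++t) {
      double eta = 0.0;
      for (int c = 0; c < pv; ++c) { xim(c, t) = xiv(t, c); eta += xiv(t, c) * beta(c); }
      h[t] = std::tanh(eta / 2.0);
      dd[t] = (1.0 - h[t] * h[t]) / 2.0;
      A[t] = (h[t] + 3.0) * (9.0 - h[t]);
      rA[t] = 1.0 / std::sqrt(A[t]);
    }
    std::vector<double> sS(m, 0.0), sw(m, 0.0);
    double* Wmem = sandwich ? W.memptr() : nullptr;

    auto do_trip = [&](int i, int j, int k, double twr) {
      bool any = false;
      for (int t = 0; t < m; ++t) {
        double w = wr(i, t) * wr(j, t) * wr(k, t) * twr;
        w3[t] = w;
        if (w > 0.0) {
          any = true;
          double f = 12.0 * kernel_phi(u(i, t), u(j, t), u(k, t),
                                       v(i, t), v(j, t), v(k, t), symmetrize) - 3.0;
          S[t] = w * (f - h[t]);
          sS[t] += S[t];
          sw[t] += w;
        } else S[t] = 0.0;
      }
      if (!any) return;
      Tn += 1.0;
      for (int s = 0; s < m - 1; ++s)
        for (int t = s + 1; t < m; ++t) {
          ca += S[s] * rA[s] * S[t] * rA[t];
          cn += w3[s] * w3[t];
        }
      if (sandwich) {
        if (!exch) {
          for (int t = 0; t < m; ++t) q[t] = dd[t] / A[t] * S[t];
        } else {
          for (int t = 0; t < m; ++t) {
            double acc = 0.0;
            for (int s = 0; s < m; ++s)
              acc += ((s == t) ? rdiag : roff) * S[s] * rA[s];
            q[t] = dd[t] * rA[t] * acc;
          }
        }
        for (int c = 0; c < p; ++c) {
          double val = 0.0;
          for (int t = 0; t < m; ++t) val += q[t] * xim(c, t);
          Wbuf[c] = val;
        }
        for (int c = 0; c < p; ++c) {
          double val = Wbuf[c];
          Wmem[c * n + i] += val;
          Wmem[c * n + j] += val;
          Wmem[c * n + k] += val;
        }
      }
    };

    if (have_trips) {
      for (arma::uword r = 0; r < trips.n_rows; ++r)
        do_trip(trips(r, 0), trips(r, 1), trips(r, 2), have_tw ? tw(r) : 1.0);
    } else if (!have_tw) {
      for (int i = 0; i < n - 2; ++i)
        for (int j = i + 1; j < n - 1; ++j)
          for (int k = j + 1; k < n; ++k)
            do_trip(i, j, k, 1.0);
    } else {
      arma::uword row = 0;
      for (int i = 0; i < n - 2; ++i)
        for (int j = i + 1; j < n - 1; ++j)
          for (int k = j + 1; k < n; ++k, ++row)
            do_trip(i, j, k, tw(row));
    }

    // assemble U and B from the per-visit sums
    if (!exch) {
      for (int t = 0; t < m; ++t) {
        U += (dd[t] / A[t] * sS[t]) * xim.col(t);
        B += (sw[t] * dd[t] * dd[t] / A[t]) * (xim.col(t) * xim.col(t).t());
      }
    } else {
      for (int t = 0; t < m; ++t) {
        double acc = 0.0;
        for (int s = 0; s < m; ++s)
          acc += ((s == t) ? rdiag : roff) * rA[s] * sS[s];
        U += (dd[t] * rA[t] * acc) * xim.col(t);
      }
      for (int s = 0; s < m; ++s)
        for (int t = 0; t < m; ++t) {
          double rinv = (s == t) ? rdiag : roff;
          B += (sw[s] * dd[s] * dd[t] * rinv * rA[s] * rA[t]) *
               (xim.col(s) * xim.col(t).t());
        }
    }
  } else {
    // ---- general path: triplet-level covariates ----
    arma::mat xi(p, m);
    std::vector<double> h(m), dd(m), A(m), rA(m);
    double* Wmem = sandwich ? W.memptr() : nullptr;

    auto do_trip = [&](int i, int j, int k, arma::uword row, double twr) {
      bool any = false;
      for (int t = 0; t < m; ++t) {
        double eta = 0.0;
        for (int c = 0; c < pv; ++c) { xi(c, t) = xiv(t, c); eta += xiv(t, c) * beta(c); }
        for (int c = 0; c < pt; ++c) { xi(pv + c, t) = xit(row, c); eta += xit(row, c) * beta(pv + c); }
        h[t] = std::tanh(eta / 2.0);
        dd[t] = (1.0 - h[t] * h[t]) / 2.0;
        A[t] = (h[t] + 3.0) * (9.0 - h[t]);
        rA[t] = 1.0 / std::sqrt(A[t]);
        double w = wr(i, t) * wr(j, t) * wr(k, t) * twr;
        w3[t] = w;
        if (w > 0.0) {
          any = true;
          double f = 12.0 * kernel_phi(u(i, t), u(j, t), u(k, t),
                                       v(i, t), v(j, t), v(k, t), symmetrize) - 3.0;
          S[t] = w * (f - h[t]);
        } else S[t] = 0.0;
      }
      if (!any) {
        // still contributes to B (weights in B are w3, all zero -> nothing)
        return;
      }
      Tn += 1.0;
      for (int s = 0; s < m - 1; ++s)
        for (int t = s + 1; t < m; ++t) {
          ca += S[s] * rA[s] * S[t] * rA[t];
          cn += w3[s] * w3[t];
        }
      if (!exch) {
        for (int t = 0; t < m; ++t) q[t] = dd[t] / A[t] * S[t];
      } else {
        for (int t = 0; t < m; ++t) {
          double acc = 0.0;
          for (int s = 0; s < m; ++s)
            acc += ((s == t) ? rdiag : roff) * S[s] * rA[s];
          q[t] = dd[t] * rA[t] * acc;
        }
      }
      for (int c = 0; c < p; ++c) {
        double val = 0.0;
        for (int t = 0; t < m; ++t) val += q[t] * xi(c, t);
        Wbuf[c] = val;
        U(c) += val;
      }
      if (sandwich)
        for (int c = 0; c < p; ++c) {
          double val = Wbuf[c];
          Wmem[c * n + i] += val;
          Wmem[c * n + j] += val;
          Wmem[c * n + k] += val;
        }
      // B accumulation
      if (!exch) {
        for (int t = 0; t < m; ++t) {
          double cb = w3[t] * dd[t] * dd[t] / A[t];
          if (cb == 0.0) continue;
          for (int c1 = 0; c1 < p; ++c1)
            for (int c2 = 0; c2 < p; ++c2)
              B(c1, c2) += cb * xi(c1, t) * xi(c2, t);
        }
      } else {
        for (int s = 0; s < m; ++s)
          for (int t = 0; t < m; ++t) {
            double rinv = (s == t) ? rdiag : roff;
            double cb = w3[s] * dd[s] * dd[t] * rinv * rA[s] * rA[t];
            if (cb == 0.0) continue;
            for (int c1 = 0; c1 < p; ++c1)
              for (int c2 = 0; c2 < p; ++c2)
                B(c1, c2) += cb * xi(c1, s) * xi(c2, t);
          }
      }
    };

    if (have_trips) {
      for (arma::uword r = 0; r < trips.n_rows; ++r)
        do_trip(trips(r, 0), trips(r, 1), trips(r, 2), r, have_tw ? tw(r) : 1.0);
    } else {
      arma::uword row = 0;
      for (int i = 0; i < n - 2; ++i)
        for (int j = i + 1; j < n - 1; ++j)
          for (int k = j + 1; k < n; ++k, ++row)
            do_trip(i, j, k, row, have_tw ? tw(row) : 1.0);
    }
  }

  return List::create(_["U"] = U, _["B"] = B,
                      _["W"] = sandwich ? wrap(W) : R_NilValue,
                      _["ca"] = ca, _["cn"] = cn, _["ntrip"] = Tn);
}

// gamma block for one dropout transition: triplets within the at-risk set.
//   G  = sum (sum_l a_l x_l) (sum_l e_l) / (sum_l a_l)
//   Jg = sum (sum_l a_l x_l) (sum_l a_l x_l)^T / (sum_l a_l)
// with a_l = p_l (1 - p_l), e_l = r_l - p_l over the triplet's members.
// X holds the at-risk subjects' predictor rows; sid their 0-based original
// subject indices (for the per-subject score sums W).
// [[Rcpp::export]]
List cpp_gamma_pass(const arma::mat& X, const arma::vec& e, const arma::vec& a,
                    const arma::ivec& sid, int n, bool sandwich) {
  const int nr = X.n_rows, q = X.n_cols;
  arma::vec G(q, arma::fill::zeros);
  arma::mat Jg(q, q, arma::fill::zeros);
  arma::mat W(sandwich ? n : 1, sandwich ? q : 1, arma::fill::zeros);
  double* Wmem = sandwich ? W.memptr() : nullptr;
  std::vector<double> ax(q);
  double Tn = 0.0;
  for (int i = 0; i < nr - 2; ++i)
    for (int j = i + 1; j < nr - 1; ++j)
      for (int k = j + 1; k < nr; ++k) {
        double sa = a(i) + a(j) + a(k);
        if (sa <= 0.0) continue;
        double inv_sa = 1.0 / sa;
        double se = e(i) + e(j) + e(k);
        for (int c = 0; c < q; ++c)
          ax[c] = a(i) * X(i, c) + a(j) * X(j, c) + a(k) * X(k, c);
        double r = se * inv_sa;
        for (int c = 0; c < q; ++c) G(c) += ax[c] * r;
        for (int c1 = 0; c1 < q; ++c1) {
          double axc = ax[c1] * inv_sa;
          for (int c2 = c1; c2 < q; ++c2)
            Jg(c1, c2) += axc * ax[c2];
        }
        if (sandwich) {
          int si = sid(i), sj = sid(j), sk = sid(k);
          for (int c = 0; c < q; ++c) {
            double val = ax[c] * r;
            Wmem[c * n + si] += val;
            Wmem[c * n + sj] += val;
            Wmem[c * n + sk] += val;
          }
        }
        Tn += 1.0;
      }
  for (int c1 = 0; c1 < q; ++c1)        // symmetrize lower triangle
    for (int c2 = 0; c2 < c1; ++c2)
      Jg(c1, c2) = Jg(c2, c1);
  return List::create(_["G"] = G, _["J"] = Jg,
                      _["W"] = sandwich ? wrap(W) : R_NilValue,
                      _["ntrip"] = Tn);
}
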