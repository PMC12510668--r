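// Steady-state firing rates of the spike-coding network.
//
// For each input y the rates solve the nonnegative quadratic program
//   r* = argmin_{r >= 0} ||y - D r||^2 + 2 T' r,
// the rate-based steady state of the competitive autoencoder network whose
// recurrence is -D'D and whose thresholds are T. Solved with a Lawson-Hanson
// style active-set method extended with the linear threshold term: on the
// passive set P the unconstrained stationarity condition is
//   (D'D)_PP r_P = (D'y)_P - T_P,
// and the KKT conditions certify optimality:
//   g = D'(D r - y) + T,  g_i = 0 for r_i > 0,  g_i >= 0 for r_i = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec solve_passive(const mat& DtD, const vec& rhs, const uvec& P,
                         double ridge) {
  mat A = DtD.submat(P, P);
  if (ridge > 0) A.diag() += ridge;
  vec b = rhs.elem(P);
  vec s;
  bool ok = solve(s, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) {
    // degenerate passive set: fall back to the minimum-norm solution
    s = pinv(A) * b;
  }
  return s;
}

// Solve one instance. rhs = D'y - T.
//
// Anti-cycling: at a degenerate face the freshly added coordinate can leave
// the passive set again with a zero-length step (its unconstrained value is
// nonpositive because the passive Gram matrix is numerically singular).
// Such a coordinate is "banned" until genuine progress is made; if every
// violating coordinate is banned the current iterate is returned, which is a
// KKT point up to the degeneracy tolerance.
static vec nnqp_one(const mat& DtD, const vec& rhs, double tol, int max_iter,
                    int* status) {
  const uword N = DtD.n_rows;
  vec r(N, fill::zeros);
  std::vector<bool> passive(N, false), banned(N, false);
  *status = 0;
  // tiny Tikhonov regularization keeps near-singular passive Gram systems
  // well posed; its effect is removed by the exact final polish below
  const double ridge = 1e-9 * (trace(DtD) / N);

  vec w = rhs; // -gradient/2 at r = 0
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // pick the most violating zero coordinate
    int j = -1;
    double wmax = tol;
    for (uword i = 0; i < N; ++i) {
      if (!passive[i] && !banned[i] && w(i) > wmax) {
        wmax = w(i); j = (int)i;
      }
    }
    if (j < 0) break; // KKT satisfied (up to bans at degenerate faces)
    passive[j] = true;
    bool progress = false;

    for (int inner = 0; inner < max_iter; ++inner) {
      uvec P(N);
      uword np = 0;
      for (uword i = 0; i < N; ++i) if (passive[i]) P(np++) = i;
      P.resize(np);
      vec s = solve_passive(DtD, rhs, P, ridge);
      if (s.min() > 0) {
        r.zeros();
        r.elem(P) = s;
        progress = true;
        break;
      }
      // step toward s until the first passive coordinate hits zero
      double alpha = 1.0;
      for (uword k = 0; k < np; ++k) {
        if (s(k) <= 0) {
          double rk = r(P(k));
          double den = rk - s(k);
          double a = den > 0 ? rk / den : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      if (alpha > 0) progress = true;
      for (uword k = 0; k < np; ++k) {
        r(P(k)) += alpha * (s(k) - r(P(k)));
      }
      for (uword k = 0; k < np; ++k) {
        if (s(k) <= 0 && r(P(k)) <= 1e-12) {
          r(P(k)) = 0.0;
          passive[P(k)] = false;
        }
      }
      if (!passive[j] && !progress) break; // j bounced straight back out
    }
    if (progress) {
      std::fill(banned.begin(), banned.end(), false);
    } else {
      passive[j] = false;
      r(j) = 0.0;
      banned[j] = true;
    }
    w = rhs - DtD * r;
  }
  if (iter >= max_iter) *status = 1; // iteration cap; best effort
  // exact (ridge-free) polish on the final support; kept only if feasible
  {
    uvec P = find(r > 0);
    if (P.n_elem > 0) {
      vec s = solve_passive(DtD, rhs, P, 0.0);
      if (s.is_finite() && s.min() > 0) {
        vec r2(N, fill::zeros);
        r2.elem(P) = s;
        // accept only if it does not worsen the KKT residual
        vec w2 = rhs - DtD * r2;
        double v2 = 0, v1 = 0;
        for (uword i = 0; i < N; ++i) {
          double a2 = (r2(i) > 0) ? std::abs(w2(i)) : std::max(w2(i), 0.0);
          double a1 = (r(i) > 0) ? std::abs(w(i)) : std::max(w(i), 0.0);
          if (a2 > v2) v2 = a2;
          if (a1 > v1) v1 = a1;
        }
        if (v2 <= v1) r = r2;
      }
    }
  }
  return r;
}

// [[Rcpp::export(name = ".nnqp_batch")]]
Rcpp::NumericMatrix nnqp_batch(const arma::mat& D, const arma::mat& Ymat,
                               const arma::vec& T, double tol = 1e-10,
                               int max_iter = 2000) {
  const uword N = D.n_cols;
  const uword G = Ymat.n_cols;
  mat DtD = D.t() * D;
  mat DtY = D.t() * Ymat;
  mat R(N, G);
  int bad = 0;
  for (uword g = 0; g < G; ++g) {
    int status = 0;
    vec rhs = DtY.col(g) - T;
    // optimality tolerance scaled to the problem magnitude
    double tol_g = tol * std::max(1.0, norm(rhs, "inf"));
    R.col(g) = nnqp_one(DtD, rhs, tol_g, max_iter, &status);
    bad += status;
  }
  if (bad > 0) {
    Rcpp::warning("%d of %d rate solves hit the iteration cap; "
                  "check KKT residuals", bad, (int)G);
  }
  // clamp solver round-off
  R.clean(1e-15);
  R.elem(find(R < 0)).zeros();
  return Rcpp::wrap(R);
}
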