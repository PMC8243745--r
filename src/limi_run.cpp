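#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// x^k for small integer k by repeated squaring; falls back to std::pow for
// non-integral exponents. The Hill coefficient and feedback exponent are
// almost always small integers, and pow() dominates the step cost otherwise.
struct FixedPow {
  double e;
  bool integral;
  long k;
  explicit FixedPow(double expnt)
    : e(expnt),
      integral(expnt == std::floor(expnt) && expnt >= 0 && expnt <= 64),
      k(static_cast<long>(expnt)) {}
  double operator()(double base) const {
    if (!integral) return std::pow(base, e);
    double r = 1.0, b = base;
    for (long kk = k; kk > 0; kk >>= 1) {
      if (kk & 1) r *= b;
      b *= b;
    }
    return r;
  }
};

// Explicit-Euler integration of the LIMI lattice system.
//
// Synchronous update: all three derivatives are evaluated on the pre-step
// snapshot, then every field is advanced by dt, negatives are clipped to
// zero, and the PV Delta clamp is reapplied. Convergence is checked on the
// derivative magnitudes of non-PV cells BEFORE each step, so the returned
// state re-evaluates below the tolerance. This mirrors limi_step() /
// limi_rhs() on the R side; equivalence is enforced by tests.
//
// residual_on_increment: check |dt * dX/dt| instead of |dX/dt|.
// [[Rcpp::export(name = ".limi_run_cpp")]]
List limi_run_cpp(NumericMatrix D0, NumericMatrix N0, NumericMatrix R0,
                  LogicalMatrix pv,
                  double beta_N, double beta_D, double beta_R,
                  double m, double n, double k_t, double k_c,
                  double gamma, double gamma_R, double k_RS,
                  double pv_delta, double dt, double tol,
                  double max_steps, bool freeze_pv_NR,
                  bool residual_on_increment) {
  const int h = D0.nrow(), w = D0.ncol(), nc = h * w;
  std::vector<double> D(D0.begin(), D0.end());
  std::vector<double> N(N0.begin(), N0.end());
  std::vector<double> R(R0.begin(), R0.end());
  std::vector<int> ispv(pv.begin(), pv.end());
  bool any_pv = false;
  for (int i = 0; i < nc; ++i) if (ispv[i]) { any_pv = true; break; }

  // neighbor index table (up, down, left, right) per cell, torus wrap
  std::vector<int> nb(4 * nc);
  for (int c = 0; c < w; ++c) {
    const int cl = (c - 1 + w) % w, cr = (c + 1) % w;
    for (int r = 0; r < h; ++r) {
      const int i = r + c * h;
      nb[4 * i + 0] = ((r - 1 + h) % h) + c * h;
      nb[4 * i + 1] = ((r + 1) % h) + c * h;
      nb[4 * i + 2] = r + cl * h;
      nb[4 * i + 3] = r + cr * h;
    }
  }

  std::vector<double> dD(nc), dN(nc), dR(nc);
  const FixedPow pow_n(n), pow_m(m);
  const double inv_kt = 1.0 / k_t, inv_kc = 1.0 / k_c;
  const double scale = residual_on_increment ? dt : 1.0;
  double steps = 0.0, resid = R_PosInf;
  bool converged = false;

  for (;;) {
    // derivatives on the current snapshot
    resid = 0.0;
    for (int i = 0; i < nc; ++i) {
      const double Davg = 0.25 * (D[nb[4 * i]] + D[nb[4 * i + 1]] +
                                  D[nb[4 * i + 2]] + D[nb[4 * i + 3]]);
      const double Navg = 0.25 * (N[nb[4 * i]] + N[nb[4 * i + 1]] +
                                  N[nb[4 * i + 2]] + N[nb[4 * i + 3]]);
      const double trans = N[i] * Davg;
      const double cis = N[i] * D[i] * inv_kc;
      dN[i] = beta_N - gamma * N[i] - trans * inv_kt - cis;
      const double s = pow_n(trans);
      const double hill = std::isfinite(s) ? s / (k_RS + s) : 1.0;
      dR[i] = beta_R * hill - gamma_R * R[i];
      dD[i] = beta_D / (1.0 + pow_m(R[i])) - gamma * D[i] -
        D[i] * Navg * inv_kt - cis;
      if (ispv[i]) {
        dD[i] = 0.0;
        if (freeze_pv_NR) { dN[i] = 0.0; dR[i] = 0.0; }
      }
      if (!(any_pv && ispv[i])) {
        double rloc = std::fabs(dN[i]);
        if (std::fabs(dD[i]) > rloc) rloc = std::fabs(dD[i]);
        if (std::fabs(dR[i]) > rloc) rloc = std::fabs(dR[i]);
        if (rloc > resid) resid = rloc;
      }
    }
    resid *= scale;
    if (resid < tol) { converged = true; break; }
    if (steps >= max_steps) { converged = false; break; }

    // synchronous Euler update, clip negatives, reapply PV clamp
    for (int i = 0; i < nc; ++i) {
      D[i] += dt * dD[i];
      N[i] += dt * dN[i];
      R[i] += dt * dR[i];
      if (D[i] < 0.0) D[i] = 0.0;
      if (N[i] < 0.0) N[i] = 0.0;
      if (R[i] < 0.0) R[i] = 0.0;
      if (ispv[i]) D[i] = pv_delta;
      if (!(std::isfinite(D[i]) && std::isfinite(N[i]) &&
            std::isfinite(R[i]))) {
        const int r1 = i % h + 1, c1 = i / h + 1;
        const char *fld = !std::isfinite(D[i]) ? "D" :
          (!std::isfinite(N[i]) ? "N" : "R");
        stop("numerical blowup: field %s non-finite at cell (%d, %d) "
             "after step %.0f", fld, r1, c1, steps + 1.0);
      }
    }
    steps += 1.0;
  }

  NumericMatrix Dout(h, w), Nout(h, w), Rout(h, w);
  std::copy(D.begin(), D.end(), Dout.begin());
  std::copy(N.begin(), N.end(), Nout.begin());
  std::copy(R.begin(), R.end(), Rout.begin());
  return List::create(_["D"] = Dout, _["N"] = Nout, _["R"] = Rout,
                      _["steps"] = steps, _["residual"] = resid,
                      _["converged"] = converged);
}
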