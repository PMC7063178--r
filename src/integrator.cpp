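// TR-BDF2 grid integrator (C++ port of the reference stepping logic in
// solver.R). One-step L-stable composite of a trapezoidal stage to
// t + gamma*h and a BDF2 stage to t + h, with modified Newton iterations and
// an embedded third-order error estimate smoothed through the stage-2
// iteration matrix.

#include <RcppArmadillo.h>
#include "tables.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".trbdf2_cpp")]]
List trbdf2_cpp(NumericVector x0, NumericVector times, List ct,
                double rtol, double atol,
                Nullable<NumericVector> clip_lower,
                Nullable<NumericVector> clip_upper, double h0) {
  const Tables tb(ct);
  const double gam = 2.0 - std::sqrt(2.0);
  const double a1c = gam / 2.0;
  const double a2c = (1.0 - gam) / (2.0 - gam);
  const double b1 = 1.0 / (gam * (2.0 - gam));
  const double b0 = (1.0 - gam) * (1.0 - gam) / (gam * (2.0 - gam));
  const double cerr = std::fabs((-3.0 * gam * gam + 4.0 * gam - 2.0) /
                                (12.0 * (2.0 - gam)));
  const int n = x0.size(), np = times.size();

  std::vector<double> ubuf(std::max(tb.n_inputs, 1));
  auto frhs = [&](const arma::vec& xx) {
    arma::vec f(n);
    tbl_rhs(tb, xx.memptr(), ubuf.data(), f.memptr());
    return f;
  };

  arma::vec x(x0.begin(), n), lo, hi;
  bool clip = clip_lower.isNotNull();
  if (clip) {
    NumericVector l(clip_lower), u(clip_upper);
    lo = arma::vec(l.begin(), n);
    hi = arma::vec(u.begin(), n);
  }
  arma::mat states(np, n);
  states.row(0) = x.t();
  arma::mat I_n = arma::eye(n, n), J(n, n);
  bool haveJ = false;
  double h = h0 > 0 ? h0 : (times[1] - times[0]) / 10.0;

  auto getJ = [&](const arma::vec& xx) {
    arma::vec f0 = frhs(xx), xp = xx;
    for (int j = 0; j < n; ++j) {
      double hj = 1e-7 * std::max(1.0, std::fabs(xx[j]));
      xp[j] = xx[j] + hj;
      arma::vec f1 = frhs(xp);
      J.col(j) = (f1 - f0) / hj;
      xp[j] = xx[j];
    }
    haveJ = true;
  };

  // modified Newton solve of z - a*f(z) - c = 0
  auto newton = [&](arma::vec z, double a, const arma::mat& M,
                    const arma::vec& c, bool& ok) -> arma::vec {
    arma::mat L, U, P;
    if (!arma::lu(L, U, P, M)) { ok = false; return z; }
    for (int it = 0; it < 10; ++it) {
      arma::vec r = z - a * frhs(z) - c;
      if (!r.is_finite()) { ok = false; return z; }
      arma::vec dz = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(L), P * r));
      z -= dz;
      double m = 0.0;
      for (int i = 0; i < n; ++i) {
        double s = std::fabs(dz[i]) /
          (atol + rtol * std::max(std::fabs(z[i]), 1e-12));
        if (s > m) m = s;
      }
      if (m < 0.05) { ok = true; return z; }
    }
    ok = false;
    return z;
  };

  for (int seg = 0; seg < np - 1; ++seg) {
    double t = times[seg], t_end = times[seg + 1];
    double hmin = std::max(1e-12, 1e-10 * (t_end - times[0]));
    while (t < t_end - 1e-12 * std::max(1.0, std::fabs(t_end))) {
      if (h > t_end - t) h = t_end - t;
      if (h < hmin)
        return List::create(_["status"] = "underflow", _["last_time"] = t);
      arma::vec f0 = frhs(x);
      if (!f0.is_finite()) {
        IntegerVector bad;
        for (int i = 0; i < n; ++i)
          if (!std::isfinite(f0[i])) bad.push_back(i + 1);
        return List::create(_["status"] = "nonfinite", _["last_time"] = t,
                            _["bad"] = bad);
      }
      if (!haveJ) getJ(x);
      arma::mat M1 = I_n - (a1c * h) * J;
      arma::mat M2 = I_n - (a2c * h) * J;
      bool ok1 = false, ok2 = false;
      arma::vec z1 = newton(x + (gam * h) * f0, a1c * h, M1,
                            x + (a1c * h) * f0, ok1);
      arma::vec z2;
      if (ok1) {
        arma::vec pred = z1 + ((1.0 - gam) / gam) * (z1 - x);
        z2 = newton(pred, a2c * h, M2, b1 * z1 - b0 * x, ok2);
      }
      if (!ok1 || !ok2) {
        getJ(x);
        h /= 2.0;
        continue;
      }
      arma::vec f1 = frhs(z1), f2 = frhs(z2);
      arma::vec dd = 2.0 * ((f2 - f1) / ((1.0 - gam) * h) -
                            (f1 - f0) / (gam * h)) / h;
      arma::vec est;
      if (!arma::solve(est, M2, cerr * h * h * h * dd))
        est = cerr * h * h * h * dd;
      double errnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        double s = est[i] / (atol + rtol * std::max(std::fabs(x[i]),
                                                    std::fabs(z2[i])));
        errnorm += s * s;
      }
      errnorm = std::sqrt(errnorm / n);
      if (std::isfinite(errnorm) && errnorm <= 1.0) {
        t += h;
        x = z2;
        if (clip) x = arma::max(arma::min(x, hi), lo);
        haveJ = false;
        h *= std::min(3.0, std::max(0.3, 0.9 * std::pow(errnorm, -1.0 / 3.0)));
      } else {
        h *= std::max(0.1, 0.9 * std::pow(errnorm + 1e-16, -1.0 / 3.0));
      }
    }
    states.row(seg + 1) = x.t();
  }
  return List::create(_["status"] = "ok",
                      _["states"] = wrap(states),
                      _["h_final"] = h);
}
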