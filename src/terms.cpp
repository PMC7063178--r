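#include "tables.h"
using namespace Rcpp;

// Compiled term table layout (built by compile_model() on the R side).
// Each additive term of a species' derivative is one row:
//   kind 0 (input_drive):  +k * u[driver]
//   kind 1 (activation):   +k * prod(x[fct]) * prod(1 + F * x[acc])
//   kind 2 (decay):        -k * x[decayof] * prod(x[fct]) / prod(1 + F * x[inh])
// Index vectors are 1-based (R convention); ptr vectors are 0-based offsets
// of length n_terms + 1 delimiting each term's slice of the flattened arrays.

double tbl_term_value(const Tables& tb, int t, const double* x,
                      const double* u) {
  double v = tb.k[t];
  switch (tb.kind[t]) {
  case 0:
    v *= u[tb.driver[t] - 1];
    break;
  case 1:
    for (int j = tb.fct_ptr[t]; j < tb.fct_ptr[t + 1]; ++j)
      v *= x[tb.fct_idx[j] - 1];
    for (int j = tb.acc_ptr[t]; j < tb.acc_ptr[t + 1]; ++j)
      v *= 1.0 + tb.acc_F[j] * x[tb.acc_idx[j] - 1];
    break;
  case 2: {
    v *= x[tb.decayof[t] - 1];
    for (int j = tb.fct_ptr[t]; j < tb.fct_ptr[t + 1]; ++j)
      v *= x[tb.fct_idx[j] - 1];
    double den = 1.0;
    for (int j = tb.inh_ptr[t]; j < tb.inh_ptr[t + 1]; ++j)
      den *= 1.0 + tb.inh_F[j] * x[tb.inh_idx[j] - 1];
    v = -v / den;
    break;
  }
  }
  return v;
}

// Resolve input values at a state. Steady-state inputs (mode 1) are derived
// from the equilibrium condition of the driven species: the drive term must
// cancel the sum of the species' remaining terms, scaled by an amplifier.
void tbl_eval_inputs(const Tables& tb, const double* x, double* u) {
  for (int i = 0; i < tb.n_inputs; ++i) {
    if (tb.imode[i] == 0) {
      u[i] = tb.ivalue[i];
    } else {
      int dt = tb.drv_term[i] - 1;  // the input_drive term for this input
      int tgt = tb.target[dt];
      double others = 0.0;
      for (int t = 0; t < tb.n_terms; ++t) {
        if (tb.target[t] == tgt && t != dt)
          others += tbl_term_value(tb, t, x, u);
      }
      if (tb.k[dt] <= 0.0)
        stop("steady-state input derivation requires a positive drive rate constant");
      u[i] = tb.iamp[i] * (-others) / tb.k[dt];
    }
  }
}

void tbl_rhs(const Tables& tb, const double* x, double* u, double* dx) {
  tbl_eval_inputs(tb, x, u);
  for (int s = 0; s < tb.n_species; ++s) dx[s] = 0.0;
  for (int t = 0; t < tb.n_terms; ++t)
    dx[tb.target[t] - 1] += tbl_term_value(tb, t, x, u);
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector x, List ct) {
  Tables tb(ct);
  NumericVector dx(tb.n_species), u(std::max(tb.n_inputs, 1));
  tbl_rhs(tb, x.begin(), u.begin(), dx.begin());
  return dx;
}

// [[Rcpp::export(name = ".inputs_cpp")]]
NumericVector inputs_cpp(NumericVector x, List ct) {
  Tables tb(ct);
  std::vector<double> u(std::max(tb.n_inputs, 1));
  tbl_eval_inputs(tb, x.begin(), u.data());
  return NumericVector(u.begin(), u.begin() + tb.n_inputs);
}

// Per-term contributions (signed), used by the R-side additivity oracle and
// by flux readouts.
// [[Rcpp::export(name = ".term_values_cpp")]]
NumericVector term_values_cpp(NumericVector x, List ct) {
  Tables tb(ct);
  std::vector<double> u(std::max(tb.n_inputs, 1));
  tbl_eval_inputs(tb, x.begin(), u.data());
  NumericVector out(tb.n_terms);
  for (int t = 0; t < tb.n_terms; ++t)
    out[t] = tbl_term_value(tb, t, x.begin(), u.data());
  return out;
}

// Forward-difference Jacobian of the full right-hand side, including the
// state dependence of steady-state-derived inputs.
// [[Rcpp::export(name = ".jac_cpp")]]
NumericMatrix jac_cpp(NumericVector x, List ct) {
  Tables tb(ct);
  int n = tb.n_species;
  std::vector<double> u(std::max(tb.n_inputs, 1)), f0(n), f1(n), xp(n);
  tbl_rhs(tb, x.begin(), u.data(), f0.data());
  NumericMatrix J(n, n);
  for (int j = 0; j < n; ++j) {
    std::copy(x.begin(), x.end(), xp.begin());
    double h = 1e-7 * std::max(1.0, std::fabs(xp[j]));
    xp[j] += h;
    tbl_rhs(tb, xp.data(), u.data(), f1.data());
    for (int i = 0; i < n; ++i) J(i, j) = (f1[i] - f0[i]) / h;
  }
  return J;
}
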