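// Shared compiled-term-table representation. See terms.cpp for the layout.
#ifndef ERINS_TABLES_H
#define ERINS_TABLES_H

#include <Rcpp.h>

struct Tables {
  Rcpp::IntegerVector target, kind, driver, decayof;
  Rcpp::NumericVector k;
  Rcpp::IntegerVector fct_ptr, fct_idx, acc_ptr, acc_idx, inh_ptr, inh_idx;
  Rcpp::NumericVector acc_F, inh_F;
  int n_species, n_terms, n_inputs;
  Rcpp::IntegerVector imode, drv_term;
  Rcpp::NumericVector ivalue, iamp;
  explicit Tables(const Rcpp::List& ct)
      : target(Rcpp::as<Rcpp::IntegerVector>(ct["target"])),
        kind(Rcpp::as<Rcpp::IntegerVector>(ct["kind"])),
        driver(Rcpp::as<Rcpp::IntegerVector>(ct["driver"])),
        decayof(Rcpp::as<Rcpp::IntegerVector>(ct["decayof"])),
        k(Rcpp::as<Rcpp::NumericVector>(ct["k"])),
        fct_ptr(Rcpp::as<Rcpp::IntegerVector>(ct["fct_ptr"])),
        fct_idx(Rcpp::as<Rcpp::IntegerVector>(ct["fct_idx"])),
        acc_ptr(Rcpp::as<Rcpp::IntegerVector>(ct["acc_ptr"])),
        acc_idx(Rcpp::as<Rcpp::IntegerVector>(ct["acc_idx"])),
        inh_ptr(Rcpp::as<Rcpp::IntegerVector>(ct["inh_ptr"])),
        inh_idx(Rcpp::as<Rcpp::IntegerVector>(ct["inh_idx"])),
        acc_F(Rcpp::as<Rcpp::NumericVector>(ct["acc_F"])),
        inh_F(Rcpp::as<Rcpp::NumericVector>(ct["inh_F"])),
        n_species(Rcpp::as<int>(ct["n_species"])),
        n_terms(Rcpp::as<int>(ct["n_terms"])),
        n_inputs(Rcpp::as<int>(ct["n_inputs"])),
        imode(Rcpp::as<Rcpp::IntegerVector>(ct["imode"])),
        drv_term(Rcpp::as<Rcpp::IntegerVector>(ct["drv_term"])),
        ivalue(Rcpp::as<Rcpp::NumericVector>(ct["ivalue"])),
        iamp(Rcpp::as<Rcpp::NumericVector>(ct["iamp"])) {}
};

double tbl_term_value(const Tables& tb, int t, const double* x, const double* u);
void tbl_eval_inputs(const Tables& tb, const double* x, double* u);
void tbl_rhs(const Tables& tb, const double* x, double* u, double* dx);

#endif
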