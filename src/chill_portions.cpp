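#include <Rcpp.h>
using namespace Rcpp;

// Hourly two-step kinetic recursion of the Dynamic chill model.
// An intermediate relaxes first-order toward a temperature-dependent
// equilibrium xs with rate ak1; whenever it reaches 1, a sigmoid-in-
// temperature fraction xi converts irreversibly to chill portions and the
// remainder carries over. Temperatures enter in Kelvin. The hourly loop is
// sequential (the reset makes it non-vectorizable), hence C++.
// [[Rcpp::export]]
NumericVector cp_dynamic_cpp(NumericVector temp_c, double slp, double tetmlt,
                             double a0, double a1, double e0, double e1) {
  int n = temp_c.size();
  NumericVector cum(n);
  double inter_s = 0.0;  // intermediate at season start
  double portions = 0.0;
  for (int i = 0; i < n; ++i) {
    double tk = temp_c[i] + 273.0;
    double ftmprt = slp * tetmlt * (tk - tetmlt) / tk;
    double sr = std::exp(ftmprt);
    double xi = sr / (1.0 + sr);
    double xs = (a0 / a1) * std::exp((e1 - e0) / tk);
    double ak1 = a1 * std::exp(-e1 / tk);
    double inter_e = xs - (xs - inter_s) * std::exp(-ak1);
    if (inter_e >= 1.0) {
      portions += xi * inter_e;
      inter_s = inter_e * (1.0 - xi);
    } else {
      inter_s = inter_e;
    }
    cum[i] = portions;
  }
  return cum;
}
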