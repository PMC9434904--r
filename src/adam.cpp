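// In-place Adam update over a parameter list. Parameter, gradient and
// moment buffers are parallel lists of equal-length numeric objects; the
// update mutates params / m / v directly to avoid per-step allocation of
// the full parameter set.
#include <Rcpp.h>

// [[Rcpp::export]]
void nn_adam_step_inplace(Rcpp::List params, Rcpp::List grads, Rcpp::List m,
                          Rcpp::List v, double lr, double b1, double b2,
                          double eps, int t) {
  const double bc1 = 1.0 - std::pow(b1, t);
  const double bc2 = 1.0 - std::pow(b2, t);
  Rcpp::CharacterVector nms = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string nm = Rcpp::as<std::string>(nms[i]);
    Rcpp::NumericVector p = params[nm];
    Rcpp::NumericVector g = grads[nm];
    Rcpp::NumericVector mi = m[nm];
    Rcpp::NumericVector vi = v[nm];
    const R_xlen_t n = p.size();
    double* pp = REAL(p);
    double* pg = REAL(g);
    double* pm = REAL(mi);
    double* pv = REAL(vi);
    for (R_xlen_t j = 0; j < n; ++j) {
      pm[j] = b1 * pm[j] + (1.0 - b1) * pg[j];
      pv[j] = b2 * pv[j] + (1.0 - b2) * pg[j] * pg[j];
      pp[j] -= lr * (pm[j] / bc1) / (std::sqrt(pv[j] / bc2) + eps);
    }
  }
}
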