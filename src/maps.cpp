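#include <Rcpp.h>
using namespace Rcpp;

// Iterate the quadratic map f(x) = 1 - alpha x^2 and return the orbit.
// [[Rcpp::export]]
NumericVector cpp_logistic_orbit(double x0, double alpha, int n) {
  NumericVector out(n);
  double x = x0;
  for (int i = 0; i < n; ++i) {
    x = 1.0 - alpha * x * x;
    out[i] = x;
  }
  return out;
}

// Orbit-average of ln|f'(x)| = ln|-2 alpha x| after a burn-in.
// Visits to an eps-neighbourhood of x = 0 are clamped to eps so a single
// superstable point cannot send the sum to -Inf.
// [[Rcpp::export]]
double cpp_logistic_lyap(double alpha, double x0, int n_iter, int burn_in,
                         double eps) {
  double x = x0;
  for (int i = 0; i < burn_in; ++i) x = 1.0 - alpha * x * x;
  double acc = 0.0;
  for (int i = 0; i < n_iter; ++i) {
    double ax = std::fabs(x);
    if (ax < eps) ax = eps;
    acc += std::log(2.0 * alpha * ax);
    x = 1.0 - alpha * x * x;
  }
  return acc / n_iter;
}
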