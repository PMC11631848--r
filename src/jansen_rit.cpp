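#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the 6-state Jansen-Rit column.
// Time unit is ms; rate constants a, b and the sigmoid ceiling e0 are per ms.
// `drive` holds the stochastic input p(t), one draw per step, pre-generated in
// R so that all randomness flows through R's RNG. Returns the net pyramidal
// membrane potential y1 - y2 (mV) for every step, burn-in included; the first
// non-finite state aborts with the offending step index.
// [[Rcpp::export]]
NumericVector jr_integrate_cpp(NumericVector drive, double dt,
                               double A, double B, double a, double b,
                               double C1, double C2, double C3, double C4,
                               double v0, double e0, double r,
                               NumericVector init) {
  const int n = drive.size();
  NumericVector out(n);
  double y0 = init[0], y1 = init[1], y2 = init[2];
  double y3 = init[3], y4 = init[4], y5 = init[5];
  const double aa = a * a, bb = b * b;
  for (int k = 0; k < n; ++k) {
    const double s1 = 2.0 * e0 / (1.0 + std::exp(r * (v0 - (y1 - y2))));
    const double s2 = 2.0 * e0 / (1.0 + std::exp(r * (v0 - C1 * y0)));
    const double s3 = 2.0 * e0 / (1.0 + std::exp(r * (v0 - C3 * y0)));
    const double d3 = A * a * s1 - 2.0 * a * y3 - aa * y0;
    const double d4 = A * a * (drive[k] + C2 * s2) - 2.0 * a * y4 - aa * y1;
    const double d5 = B * b * C4 * s3 - 2.0 * b * y5 - bb * y2;
    y0 += dt * y3; y1 += dt * y4; y2 += dt * y5;
    y3 += dt * d3; y4 += dt * d4; y5 += dt * d5;
    out[k] = y1 - y2;
    if (!std::isfinite(out[k])) {
      stop("Jansen-Rit integration became non-finite at step %d "
           "(step size too large for these parameters)", k + 1);
    }
  }
  return out;
}
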