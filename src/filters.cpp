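#include <Rcpp.h>
using namespace Rcpp;

// One second-order IIR section, direct form II transposed.
// The state is initialised as if the input had been constant at x0
// forever, so a step input produces its steady-state response from the
// first sample (no edge transient).
// [[Rcpp::export(name = ".biquad_filter")]]
NumericVector biquad_filter(NumericVector b, NumericVector a,
                            NumericVector x, double x0) {
  if (b.size() != 3 || a.size() != 3 || a[0] == 0.0)
    stop("biquad expects length-3 b and a with a[0] != 0");
  const double a0 = a[0];
  const double b0 = b[0] / a0, b1 = b[1] / a0, b2 = b[2] / a0;
  const double a1 = a[1] / a0, a2 = a[2] / a0;
  const double h1 = (b0 + b1 + b2) / (1.0 + a1 + a2);
  // steady state for constant input x0:
  //   z2 = (b2 - a2*h1)*x0 ;  z1 = (b1 - a1*h1)*x0 + z2
  double z2 = (b2 - a2 * h1) * x0;
  double z1 = (b1 - a1 * h1) * x0 + z2;
  const R_xlen_t n = x.size();
  NumericVector y(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}
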