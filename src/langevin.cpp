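#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama recursion in U(x) = H * (x^2 - 1)^2.
// Noise increments are supplied from R so that all randomness flows
// through the caller's seed.
// [[Rcpp::export]]
NumericVector langevin_double_well(int n, double x0, double H, double gamma,
                                   double RT, double dt,
                                   NumericVector noise) {
  NumericVector x(n);
  double xi = x0;
  const double mob = dt / gamma;
  const double amp = std::sqrt(2.0 * RT * dt / gamma);
  for (int i = 0; i < n; ++i) {
    double force = -4.0 * H * xi * (xi * xi - 1.0);
    xi += force * mob + amp * noise[i];
    x[i] = xi;
  }
  return x;
}
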