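#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler stepping of the 1D diffusion equation dC/dt = D d2C/dX2 on a
// cell-centred grid with reflecting (no-flux) boundaries: ghost values mirror
// the boundary cell (C[-1] = C[0], C[n] = C[n-1]), so the plain sum of C is
// conserved exactly (up to floating-point rounding).
//
// [[Rcpp::export(name = ".euler_steps")]]
NumericVector euler_steps(NumericVector concentration, double D, double dx,
                          double dt, int nsteps) {
  int n = concentration.size();
  if (n < 3) stop("profile must have at least 3 points");
  double alpha = D * dt / (dx * dx);
  if (alpha > 0.25 + 1e-12)
    stop("unstable step: D*dt/dx^2 = %g exceeds 0.25", alpha);
  std::vector<double> c(concentration.begin(), concentration.end());
  std::vector<double> lap(n);
  for (int s = 0; s < nsteps; ++s) {
    lap[0] = c[1] - c[0];
    lap[n - 1] = c[n - 2] - c[n - 1];
    for (int i = 1; i < n - 1; ++i)
      lap[i] = c[i - 1] - 2.0 * c[i] + c[i + 1];
    for (int i = 0; i < n; ++i)
      c[i] += alpha * lap[i];
  }
  return wrap(c);
}
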