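#include <Rcpp.h>
using namespace Rcpp;

// Method-of-lines right-hand side for the two-compartment radial spherical
// model. State is interleaved: y[2*i] = u1 at node i, y[2*i + 1] = u2 at
// node i, on a uniform grid r_i = i*h, i = 0..N-1 (r_0 = 0, r_{N-1} = L).
//
// Diffusion uses the conservative finite-volume form of the spherical
// radial Laplacian (1/r^2) d/dr (r^2 D du/dr): face fluxes r^2 D du/dr
// divided by the cell volume integral of r^2 dr. At r = 0 this reproduces
// the symmetry limit 6 D (u_1 - u_0) / h^2 = 3 D u''(0). No-flux boundaries
// are imposed by zero diffusive face flux at both ends.
//
// Advection is the planar form -d/dr(A u) (as the model is written, not the
// full spherical divergence), discretized with centered face averages
// G_{i+1/2} = A (u_i + u_{i+1}) / 2, so interior nodes see the classical
// central difference -(A u_{i+1} - A u_{i-1}) / (2h); the advective face
// flux is set to 0 at both boundaries.
//
// The logistic term rho*u*(1 - (u1+u2)/K) is evaluated as 0 when K == 0
// (only admissible when that compartment carries no mass; validated on the
// R side).
// [[Rcpp::export]]
NumericVector rhs_radial_two_pop(double t, NumericVector y,
                                 double D1, double D2,
                                 double rho1, double rho2,
                                 double K1, double K2,
                                 double A1, double A2,
                                 double h, int N) {
  NumericVector dy(2 * N);
  // cell volumes: integral of r^2 dr over [max(r_i - h/2, 0), min(r_i + h/2, L)]
  // faces at r = (i + 1/2) h for i = 0..N-2
  for (int c = 0; c < 2; ++c) {
    double D = (c == 0) ? D1 : D2;
    double A = (c == 0) ? A1 : A2;
    double Fprev = 0.0; // r^2 D du/dr at the left face (zero at r = 0)
    double Gprev = 0.0; // advective flux A u at the left face (zero, no-flux)
    for (int i = 0; i < N; ++i) {
      double ri = i * h;
      double rl = (i == 0) ? 0.0 : ri - 0.5 * h;
      double rr = (i == N - 1) ? ri : ri + 0.5 * h;
      double V = (rr * rr * rr - rl * rl * rl) / 3.0;
      double Fnext = 0.0, Gnext = 0.0;
      if (i < N - 1) {
        double rf = ri + 0.5 * h;
        double ui = y[2 * i + c], uip = y[2 * (i + 1) + c];
        Fnext = rf * rf * D * (uip - ui) / h;
        Gnext = A * 0.5 * (ui + uip);
      }
      double u1 = y[2 * i];
      double u2 = y[2 * i + 1];
      double u = y[2 * i + c];
      double K = (c == 0) ? K1 : K2;
      double rho = (c == 0) ? rho1 : rho2;
      double reaction = (K > 0.0) ? rho * u * (1.0 - (u1 + u2) / K) : 0.0;
      // planar advection divergence: -(G_{i+1/2} - G_{i-1/2}) / h
      dy[2 * i + c] = (Fnext - Fprev) / V + reaction - (Gnext - Gprev) / h;
      Fprev = Fnext;
      Gprev = Gnext;
    }
  }
  return dy;
}
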