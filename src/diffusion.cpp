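// One-dimensional forward (Kolmogorov) diffusion of the allele-frequency
// density under genetic drift, selection with arbitrary dominance, and a
// constant mutational influx near the q = 0 boundary.
//
// Time is measured in units of 2*Nanc generations.  With x the mutant
// frequency, nu = N/Nanc the relative population size, gamma = 2*Nanc*s
// (s > 0 deleterious under the fitness convention 1, 1-2sh, 1-2s):
//
//   dphi/dt = -d/dx[ M phi ] + (1/2) d^2/dx^2 [ V phi ] + source
//   V = x(1-x)/nu,   M = -2 gamma x(1-x) (h + (1-2h) x)
//
// Discretized in conservative form with Scharfetter-Gummel (exponentially
// fitted) edge fluxes on a non-uniform interior grid, absorbing boundaries
// at x = 0 and 1, and a theta-scheme in time (theta = 0.5, Crank-Nicolson).
// The mutational source vector is supplied by the caller; choosing
// source = -L[1/x] at neutrality makes phi = theta/x an exact discrete
// neutral equilibrium.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bernoulli function z / (e^z - 1), stable for all z.
static inline double bern(double z) {
  if (std::fabs(z) < 1e-10) return 1.0 - 0.5 * z;
  if (z > 700.0) return 0.0;
  if (z < -700.0) return -z;
  return z / std::expm1(z);
}

struct Operator {
  // J_{j+1/2} = P[j] * phi[j] - Q[j] * phi[j+1], edges 0..G (phantom ends)
  std::vector<double> P, Q, invDx;
  int G;
};

// Assemble SG edge coefficients for given gamma, h, nu.
static void assemble(const NumericVector& x, double gamma, double h,
                     double nu, Operator& op) {
  int G = x.size();
  op.G = G;
  op.P.assign(G + 1, 0.0);
  op.Q.assign(G + 1, 0.0);
  op.invDx.assign(G, 0.0);
  for (int j = 0; j < G; ++j) {
    double lo = (j == 0) ? 0.0 : x[j - 1];
    double hi = (j == G - 1) ? 1.0 : x[j + 1];
    op.invDx[j] = 2.0 / (hi - lo);
  }
  for (int e = 0; e <= G; ++e) {
    double xl = (e == 0) ? 0.0 : x[e - 1];
    double xr = (e == G) ? 1.0 : x[e];
    double he = xr - xl;
    double xm = 0.5 * (xl + xr);
    double vd = xm * (1.0 - xm);
    double D = 0.5 * vd / nu;                        // diffusion coeff
    double A = -2.0 * gamma * vd * (h + (1.0 - 2.0 * h) * xm)
               - 0.5 * (1.0 - 2.0 * xm) / nu;        // drift A = M - V'/2
    double w = A * he / D;
    op.P[e] = (D / he) * bern(-w);
    op.Q[e] = (D / he) * bern(w);
  }
}

// L phi at all nodes (phantom boundary density = 0).
static void applyL(const Operator& op, const std::vector<double>& phi,
                   std::vector<double>& out) {
  int G = op.G;
  for (int j = 0; j < G; ++j) {
    double Jl = (j == 0) ? -op.Q[0] * phi[0]
                         : op.P[j] * phi[j - 1] - op.Q[j] * phi[j];
    double Jr = (j == G - 1) ? op.P[G] * phi[G - 1]
                             : op.P[j + 1] * phi[j] - op.Q[j + 1] * phi[j + 1];
    out[j] = (Jl - Jr) * op.invDx[j];
  }
}

// [[Rcpp::export(name = ".diffusionApplyL")]]
NumericVector diffusionApplyL(NumericVector phi, NumericVector x,
                              double gamma, double h, double nu) {
  Operator op;
  assemble(x, gamma, h, nu, op);
  std::vector<double> p(phi.begin(), phi.end()), out(phi.size());
  applyL(op, p, out);
  return NumericVector(out.begin(), out.end());
}

// Thomas solve of (I - w L) u = rhs for tridiagonal L given by op.
static void solveImplicit(const Operator& op, double w,
                          const std::vector<double>& rhs,
                          std::vector<double>& u,
                          std::vector<double>& cw, std::vector<double>& dw) {
  int G = op.G;
  // tridiagonal of L: sub a_j = P[j]*invDx, diag b_j = -(Q[j]+P[j+1])*invDx,
  // super c_j = Q[j+1]*invDx
  cw.assign(G, 0.0);
  dw.assign(G, 0.0);
  double bj = 1.0 + w * (op.Q[0] + op.P[1]) * op.invDx[0];
  double cj = -w * op.Q[1] * op.invDx[0];
  cw[0] = cj / bj;
  dw[0] = rhs[0] / bj;
  for (int j = 1; j < G; ++j) {
    double aj = -w * op.P[j] * op.invDx[j];
    bj = 1.0 + w * (op.Q[j] + op.P[j + 1]) * op.invDx[j];
    cj = (j < G - 1) ? -w * op.Q[j + 1] * op.invDx[j] : 0.0;
    double m = bj - aj * cw[j - 1];
    cw[j] = cj / m;
    dw[j] = (rhs[j] - aj * dw[j - 1]) / m;
  }
  u[G - 1] = dw[G - 1];
  for (int j = G - 2; j >= 0; --j) u[j] = dw[j] - cw[j] * u[j + 1];
}

// Integrate one epoch of duration tau (2*Nanc units).  nu interpolates
// geometrically from nu0 to nu1 when expMode is true, else stays at nu0.
// [[Rcpp::export(name = ".diffusionIntegrate")]]
NumericVector diffusionIntegrate(NumericVector phi, NumericVector x,
                                 double gamma, double h, double nu0,
                                 double nu1, double tau, bool expMode,
                                 double dt, NumericVector source,
                                 double thetaScheme) {
  int G = x.size();
  if (tau <= 0) return clone(phi);
  int nstep = (int)std::ceil(tau / dt - 1e-12);
  if (nstep < 1) nstep = 1;
  double step = tau / nstep;
  std::vector<double> cur(phi.begin(), phi.end()), rhs(G), lphi(G), nxt(G),
      cw(G), dw(G);
  Operator op;
  double lr = expMode ? std::log(nu1 / nu0) : 0.0;
  for (int k = 0; k < nstep; ++k) {
    double tmid = (k + 0.5) * step / tau;
    double nu = expMode ? nu0 * std::exp(lr * tmid) : nu0;
    assemble(x, gamma, h, nu, op);
    applyL(op, cur, lphi);
    double we = (1.0 - thetaScheme) * step;   // explicit weight
    double wi = thetaScheme * step;           // implicit weight
    for (int j = 0; j < G; ++j)
      rhs[j] = cur[j] + we * lphi[j] + step * source[j];
    solveImplicit(op, wi, rhs, nxt, cw, dw);
    for (int j = 0; j < G; ++j) cur[j] = (nxt[j] > 0.0) ? nxt[j] : 0.0;
  }
  return NumericVector(cur.begin(), cur.end());
}
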