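#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Semi-discrete (method-of-lines) right-hand side of the mean-field model:
// finite-volume discretisation of the four extension-density equations
//   P_b,t + J_b,y =  omega_on P_u - omega_0 e^{gamma y} P_b
//   P_u,t + J_u,y = -omega_on P_u + omega_0 e^{gamma y} P_b
// with J_b = v_b P_b - D_b P_b,y,  J_u = v_u P_u - Gamma D_u P_u,y,
// v_b = 1 - y -/+ dz/dt, v_u = -Gamma y, zero flux at y = 0 and y = y_max,
// coupled to xi dz/dt = -K z - (F^- - F^+),  F+- = N Int y P_b+- dy.
// Advection is first-order upwind on faces, diffusion is central; zero
// boundary flux makes the per-cortex probability conserved bit-exactly.
//
// State layout: [Pb+ (M), Pb- (M), Pu+ (M), Pu- (M), z].

// [[Rcpp::export]]
NumericVector fp_rhs_cpp(NumericVector state, int M, double h,
                         NumericVector ycent, NumericVector yface,
                         NumericVector unbind_c, double K, double xi,
                         double N, double D_b, double D_u, double Gamma,
                         double omega_on) {
  const double *Pbp = state.begin();
  const double *Pbm = Pbp + M;
  const double *Pup = Pbm + M;
  const double *Pum = Pup + M;
  const double z = state[4 * M];
  NumericVector deriv(4 * M + 1);
  double *dbp = deriv.begin();
  double *dbm = dbp + M;
  double *dup = dbm + M;
  double *dum = dup + M;

  // pulling forces (midpoint quadrature) and spindle velocity
  double Fp = 0.0, Fm = 0.0;
  for (int j = 0; j < M; ++j) {
    Fp += ycent[j] * Pbp[j];
    Fm += ycent[j] * Pbm[j];
  }
  Fp *= N * h; Fm *= N * h;
  const double dzdt = (-K * z - (Fm - Fp)) / xi;
  deriv[4 * M] = dzdt;

  const double GDu = Gamma * D_u;
  // interior faces f = 1..M-1 between cells f-1 and f
  double Jbp_prev = 0.0, Jbm_prev = 0.0, Jup_prev = 0.0, Jum_prev = 0.0;
  for (int f = 1; f <= M; ++f) {
    double Jbp = 0.0, Jbm = 0.0, Jup = 0.0, Jum = 0.0;
    if (f < M) {
      const double yf = yface[f];
      double vbp = 1.0 - yf - dzdt;
      double vbm = 1.0 - yf + dzdt;
      double vu = -Gamma * yf;
      Jbp = (vbp > 0 ? vbp * Pbp[f - 1] : vbp * Pbp[f])
            - D_b * (Pbp[f] - Pbp[f - 1]) / h;
      Jbm = (vbm > 0 ? vbm * Pbm[f - 1] : vbm * Pbm[f])
            - D_b * (Pbm[f] - Pbm[f - 1]) / h;
      Jup = vu * Pup[f] - GDu * (Pup[f] - Pup[f - 1]) / h;   // vu < 0
      Jum = vu * Pum[f] - GDu * (Pum[f] - Pum[f - 1]) / h;
    }
    const int j = f - 1;
    const double react_p = omega_on * Pup[j] - unbind_c[j] * Pbp[j];
    const double react_m = omega_on * Pum[j] - unbind_c[j] * Pbm[j];
    dbp[j] = -(Jbp - Jbp_prev) / h + react_p;
    dbm[j] = -(Jbm - Jbm_prev) / h + react_m;
    dup[j] = -(Jup - Jup_prev) / h - react_p;
    dum[j] = -(Jum - Jum_prev) / h - react_m;
    Jbp_prev = Jbp; Jbm_prev = Jbm; Jup_prev = Jup; Jum_prev = Jum;
  }
  return deriv;
}
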