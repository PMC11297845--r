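#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Event-driven simulation of 2N force generators as biased random walks on a
// discretised extension axis, coupled to the spindle force balance
//   xi dz/dt = -K z + dy * (sum_i+  -  sum_i-)   (sums over bound walkers).
// Rates are frozen between events; if the sampled waiting time exceeds dt_max
// the spindle is advanced by dt_max (exact linear-ODE update with extensions
// fixed) and rates are refreshed without an event.  Uses R's RNG so that
// set.seed() in R makes runs reproducible.

static inline double advance_z(double z, double S, double K, double xi,
                               double s) {
  if (K > 0.0) {
    double zinf = S / K;
    return zinf + (z - zinf) * std::exp(-K * s / xi);
  }
  return z + (S / xi) * s;
}

// Hop-rate splitting for a walk with drift v and diffusivity D on step dy:
// central splitting (up = D/dy^2 + v/(2 dy), down = D/dy^2 - v/(2 dy))
// matches mean v*t AND variance 2*D*t exactly; where it would go negative
// (|v| dy > 2 D) fall back to upwind splitting (exact mean, variance
// 2*D*t + |v|*dy*t, i.e. O(dy) excess).
static inline void hop_rates(double v, double D, double dy, double dy2,
                             double &up, double &dn) {
  double c = 0.5 * v / dy, base = D / dy2;
  if (base >= std::fabs(c)) {
    up = base + c; dn = base - c;
  } else if (v > 0) {
    up = base + v / dy; dn = base;
  } else {
    up = base; dn = base - v / dy;
  }
}

// [[Rcpp::export]]
List gillespie_core(double xi, double K, double omega_on, double omega_0,
                    double y_max, double gamma, double D_b, double D_u,
                    double Gamma, int N, double delta_y, double dt_max,
                    double t_end, double z0, double record_every) {
  const int m = (int)std::lround(y_max / delta_y);   // extension index 0..m
  const double dy = y_max / m;
  const double dy2 = dy * dy;
  const int W = 2 * N;                               // walkers; k < N is '+'

  // static rate tables on the extension grid
  std::vector<double> yv(m + 1), unbind(m + 1), uu_up(m + 1), uu_dn(m + 1),
      u_tot(m + 1);
  const double GDu = Gamma * D_u;
  for (int i = 0; i <= m; ++i) {
    yv[i] = i * dy;
    unbind[i] = omega_0 * std::exp(gamma * yv[i]);
    // unbound: drift -Gamma*y (towards 0), diffusivity Gamma*D_u, reflecting
    double up, dn;
    hop_rates(-Gamma * yv[i], GDu, dy, dy2, up, dn);
    uu_up[i] = (i < m) ? up : 0.0;
    uu_dn[i] = (i > 0) ? dn : 0.0;
    u_tot[i] = uu_up[i] + uu_dn[i] + omega_on;
  }

  // walker state: all start unbound at y = 0
  std::vector<int> idx(W, 0);
  std::vector<char> bound(W, 0);
  // cached per-walker total rates; bound hop rates recomputed every freeze
  std::vector<double> wtot(W), b_up(W), b_dn(W);
  double tot_u = 0.0;
  for (int k = 0; k < W; ++k) { wtot[k] = u_tot[0]; tot_u += u_tot[0]; }

  int nbp = 0, nbm = 0;
  long sb_p = 0, sb_m = 0;     // sum of bound extension indices per cortex
  long su_p = 0, su_m = 0;     // sum of unbound extension indices per cortex

  const int nrec = (int)std::floor(t_end / record_every) + 1;
  NumericVector rt(nrec), rz(rt.size()), r_nbp(nrec), r_nbm(nrec),
      r_ybp(nrec), r_ybm(nrec), r_yup(nrec), r_yum(nrec);
  int irec = 0;   // record times are irec * record_every (no accumulation)

  double t = 0.0, z = z0;
  while (t < t_end) {
    double S = dy * (double)(sb_p - sb_m);
    double dzdt = (-K * z + S) / xi;

    // refresh bound-walker rates (they depend on dz/dt) and total rate
    double tot_b = 0.0;
    for (int k = 0; k < W; ++k) {
      if (!bound[k]) continue;
      int i = idx[k];
      double v = 1.0 - yv[i] - (k < N ? dzdt : -dzdt);
      double up, dn;
      hop_rates(v, D_b, dy, dy2, up, dn);
      if (i == m) up = 0.0;
      if (i == 0) dn = 0.0;
      b_up[k] = up; b_dn[k] = dn;
      wtot[k] = up + dn + unbind[i];
      tot_b += wtot[k];
    }
    double total = tot_b + tot_u;

    double tau = (total > 0.0) ? -std::log(unif_rand()) / total : R_PosInf;
    bool event = (tau <= dt_max);
    double s_adv = event ? tau : dt_max;
    if (t + s_adv > t_end) { s_adv = t_end - t; event = false; }

    // record at regular times crossed during this advance (state frozen)
    while (irec < nrec && irec * record_every <= t + s_adv + 1e-9) {
      double tr = irec * record_every;
      rt[irec] = tr;
      rz[irec] = advance_z(z, S, K, xi, tr > t ? tr - t : 0.0);
      r_nbp[irec] = nbp; r_nbm[irec] = nbm;
      r_ybp[irec] = nbp > 0 ? dy * (double)sb_p / nbp : NA_REAL;
      r_ybm[irec] = nbm > 0 ? dy * (double)sb_m / nbm : NA_REAL;
      r_yup[irec] = (N - nbp) > 0 ? dy * (double)su_p / (N - nbp) : NA_REAL;
      r_yum[irec] = (N - nbm) > 0 ? dy * (double)su_m / (N - nbm) : NA_REAL;
      ++irec;
    }

    z = advance_z(z, S, K, xi, s_adv);
    t += s_adv;
    if (!event) continue;

    // select the event by cumulative-rate inversion
    double r = unif_rand() * total, acc = 0.0;
    int k = -1;
    for (int kk = 0; kk < W; ++kk) {
      acc += wtot[kk];
      if (r < acc) { k = kk; break; }
    }
    if (k < 0) k = W - 1;  // guard against roundoff at the top end
    double rk = r - (acc - wtot[k]);
    int i = idx[k];
    bool plus = (k < N);
    if (bound[k]) {
      if (rk < b_up[k]) {
        idx[k] = i + 1; if (plus) ++sb_p; else ++sb_m;
      } else if (rk < b_up[k] + b_dn[k]) {
        idx[k] = i - 1; if (plus) --sb_p; else --sb_m;
      } else {  // unbind
        bound[k] = 0;
        if (plus) { --nbp; sb_p -= i; su_p += i; }
        else      { --nbm; sb_m -= i; su_m += i; }
        wtot[k] = u_tot[i]; tot_u += wtot[k];
      }
    } else {
      tot_u -= wtot[k];
      if (rk < uu_up[i]) {
        idx[k] = i + 1; if (plus) ++su_p; else ++su_m;
        wtot[k] = u_tot[i + 1]; tot_u += wtot[k];
      } else if (rk < uu_up[i] + uu_dn[i]) {
        idx[k] = i - 1; if (plus) --su_p; else --su_m;
        wtot[k] = u_tot[i - 1]; tot_u += wtot[k];
      } else {  // bind
        bound[k] = 1;
        if (plus) { ++nbp; sb_p += i; su_p -= i; }
        else      { ++nbm; sb_m += i; su_m -= i; }
        // bound rates refreshed at the top of the loop
      }
    }
  }

  return List::create(_["t"] = rt, _["z"] = rz,
                      _["n_b_plus"] = r_nbp, _["n_b_minus"] = r_nbm,
                      _["mean_yb_plus"] = r_ybp, _["mean_yb_minus"] = r_ybm,
                      _["mean_yu_plus"] = r_yup, _["mean_yu_minus"] = r_yum);
}

// Free biased random walk with the same hop-rate construction (no
// boundaries, no binding): used to validate that the walk's first two
// moments reproduce advection-diffusion (mean v*t, variance 2*D*t).
// [[Rcpp::export]]
NumericVector walker_displacements(int nsamp, double v, double D, double dy,
                                   double t_end) {
  NumericVector out(nsamp);
  double up, dn;
  hop_rates(v, D, dy, dy * dy, up, dn);
  const double total = up + dn, pup = up / total;
  for (int s = 0; s < nsamp; ++s) {
    double t = 0.0;
    long j = 0;
    for (;;) {
      t += -std::log(unif_rand()) / total;
      if (t > t_end) break;
      if (unif_rand() < pup) ++j; else --j;
    }
    out[s] = j * dy;
  }
  return out;
}
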