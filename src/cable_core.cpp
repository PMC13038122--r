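#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Implicit (theta-method) integrator for branched passive/HH cables under
// extracellular stimulation and conductance-based synaptic drive.
//
// Units: mV, ms, uS, nF, nA. Compartments must be topologically sorted
// (parent index < own index, root = -1). The linear solve per step uses
// Hines elimination on the tree (leaves -> root, then back-substitution),
// which is exact and unconditionally stable for the implicit part.
//
// Gating uses the classic squid Na/K kinetics with a global rate scale
// (Q10 temperature factor), advanced by exact exponential (Rush-Larsen)
// updates evaluated at the previous voltage. For the giant settling steps
// this update collapses to x = x_inf(v), as required for steady state.

static inline double safe_exp(double x) {
  if (x > 700.0) return std::exp(700.0);
  if (x < -700.0) return 0.0;
  return std::exp(x);
}

// vtrap: x / (exp(x/y) - 1) with removable singularity at x = 0
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (safe_exp(x / y) - 1.0);
}

static inline void hh_rates(double v, double* a, double* b) {
  // a[0],b[0]: m; a[1],b[1]: h; a[2],b[2]: n  (1/ms at 6.3 C)
  a[0] = 0.1 * vtrap(-(v + 40.0), 10.0);
  b[0] = 4.0 * safe_exp(-(v + 65.0) / 18.0);
  a[1] = 0.07 * safe_exp(-(v + 65.0) / 20.0);
  b[1] = 1.0 / (1.0 + safe_exp(-(v + 35.0) / 10.0));
  a[2] = 0.01 * vtrap(-(v + 55.0), 10.0);
  b[2] = 0.125 * safe_exp(-(v + 65.0) / 80.0);
}

// [[Rcpp::export]]
List cable_core_integrate(IntegerVector parent, NumericVector g_axial,
                          NumericVector cm, NumericVector gna,
                          NumericVector gk, NumericVector gl, double ena,
                          double ek, double el, double rate_scale, double dt,
                          int nsteps, double theta, NumericVector v0,
                          NumericMatrix gate0, NumericVector psi,
                          NumericVector wave, List syn_bin_g,
                          IntegerVector syn_bin, NumericVector syn_w,
                          NumericVector e_rev, double mg, bool nmda_gated,
                          IntegerVector record) {
  const int n = parent.size();
  const int nt = nsteps + 1;
  const int nrec = record.size();

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> m(n), h(n), nn(n);
  bool init_gates = (gate0.nrow() != n);
  double a[3], b[3];
  for (int i = 0; i < n; ++i) {
    if (init_gates) {
      hh_rates(v[i], a, b);
      m[i] = a[0] / (a[0] + b[0]);
      h[i] = a[1] / (a[1] + b[1]);
      nn[i] = a[2] / (a[2] + b[2]);
    } else {
      m[i] = gate0(i, 0);
      h[i] = gate0(i, 1);
      nn[i] = gate0(i, 2);
    }
  }

  bool have_stim = (psi.size() == n) && (wave.size() >= nt);
  int nsyn = syn_bin_g.size();  // 0 or 4 receptor bin-conductance matrices
  std::vector<NumericMatrix> gs;
  for (int r = 0; r < nsyn; ++r) gs.push_back(as<NumericMatrix>(syn_bin_g[r]));

  NumericMatrix vrec(nrec, nt);
  for (int r = 0; r < nrec; ++r) vrec(r, 0) = v[record[r]];

  std::vector<double> d(n), rhs(n), od(n), vext_old(n, 0.0), vext_new(n, 0.0);
  if (have_stim)
    for (int i = 0; i < n; ++i) vext_old[i] = psi[i] * wave[0];

  bool diverged = false;
  int fail_step = -1;

  for (int s = 1; s < nt && !diverged; ++s) {
    // 1) gating update (Rush-Larsen, rates at previous v)
    for (int i = 0; i < n; ++i) {
      if (gna[i] <= 0.0 && gk[i] <= 0.0) continue;
      hh_rates(v[i], a, b);
      for (int g = 0; g < 3; ++g) {
        double rsum = rate_scale * (a[g] + b[g]);
        double xinf = a[g] / (a[g] + b[g]);
        double e = (rsum * dt > 50.0) ? 0.0 : std::exp(-rsum * dt);
        double* x = (g == 0) ? &m[i] : (g == 1) ? &h[i] : &nn[i];
        *x = xinf + (*x - xinf) * e;
      }
    }

    if (have_stim)
      for (int i = 0; i < n; ++i) vext_new[i] = psi[i] * wave[s];

    // 2) assemble theta-method system
    for (int i = 0; i < n; ++i) {
      double gmem = gna[i] * m[i] * m[i] * m[i] * h[i];
      double bmem = gmem * ena;
      double gK4 = gk[i] * nn[i] * nn[i] * nn[i] * nn[i];
      gmem += gK4;
      bmem += gK4 * ek;
      gmem += gl[i];
      bmem += gl[i] * el;
      // synaptic conductances, theta-weighted in time
      if (nsyn > 0 && syn_bin[i] >= 0) {
        int bi = syn_bin[i];
        for (int r = 0; r < nsyn; ++r) {
          double gq = syn_w[i] * (theta * gs[r](bi, s) +
                                  (1.0 - theta) * gs[r](bi, s - 1));
          if (nmda_gated && r == 1)  // NMDA magnesium block at local v
            gq /= (1.0 + 0.28 * mg * safe_exp(-0.062 * v[i]));
          gmem += gq;
          bmem += gq * e_rev[r];
        }
      }
      d[i] = cm[i] / dt + theta * gmem;
      rhs[i] = (cm[i] / dt - (1.0 - theta) * gmem) * v[i] + bmem;
      od[i] = 0.0;
    }

    // axial terms: membrane eq couples through (v_m + v_ext) differences
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      double g = g_axial[i];
      d[i] += theta * g;
      d[p] += theta * g;
      od[i] = -theta * g;
      double dext = theta * (vext_new[p] - vext_new[i]) +
                    (1.0 - theta) * (vext_old[p] - vext_old[i]);
      double dold = v[p] - v[i];
      rhs[i] += g * ((1.0 - theta) * dold + dext);
      rhs[p] -= g * ((1.0 - theta) * dold + dext);
    }

    // 3) Hines solve: eliminate leaves -> root, back-substitute
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = od[i] / d[i];
      d[p] -= f * od[i];
      rhs[p] -= f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] - od[i] * v[parent[i]]) / d[i];

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 1000.0) {
        diverged = true;
        fail_step = s;
        break;
      }
    }
    for (int r = 0; r < nrec; ++r) vrec(r, s) = v[record[r]];
    std::swap(vext_old, vext_new);
  }

  NumericVector vfin(v.begin(), v.end());
  NumericMatrix gfin(n, 3);
  for (int i = 0; i < n; ++i) {
    gfin(i, 0) = m[i];
    gfin(i, 1) = h[i];
    gfin(i, 2) = nn[i];
  }
  return List::create(_["v"] = vrec, _["v_final"] = vfin,
                      _["gates_final"] = gfin, _["diverged"] = diverged,
                      _["fail_step"] = fail_step);
}
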