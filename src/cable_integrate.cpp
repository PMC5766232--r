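// Discrete cable integrator.
//
// Semi-implicit scheme: the linear axial coupling (and passive membrane
// leaks of myelin compartments) are advanced with Crank-Nicolson on the
// tridiagonal system; gating variables use the Rush-Larsen exponential
// update at the start-of-step voltage; the nonlinear ionic current is
// evaluated explicitly at the start-of-step voltage. The left-hand matrix
// is constant, so its Thomas factorisation is computed once.
//
// Units: mV, ms, nA, nF, uS (consistent: nF*mV/ms = nA = uS*mV).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double xexp(double x) { // x / (1 - exp(-x)), stable at 0
  if (std::fabs(x) < 1e-7) return 1.0 + 0.5 * x;
  return x / (1.0 - std::exp(-x));
}

struct Rates {
  double am, bm, ah, bh, an, bn;
};

static inline Rates hh_rates(double v) {
  Rates r;
  r.am = xexp((v + 40.0) / 10.0);
  r.bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.an = 0.1 * xexp((v + 55.0) / 10.0);
  r.bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return r;
}

// [[Rcpp::export]]
List cable_integrate_cpp(NumericVector cap_nF,
                         NumericVector g_axial_uS,
                         LogicalVector is_node,
                         NumericVector area_cm2,
                         NumericVector g_pas_uS,
                         NumericVector e_pas_mV,
                         List membrane,
                         double dt,
                         int n_steps,
                         double v_init,
                         double threshold,
                         IntegerVector record, // 1-based compartment indices
                         int stim_comp,        // 1-based
                         double stim_amp_nA,
                         double stim_onset_ms,
                         double stim_dur_ms,
                         int stop_comp) {      // 1-based; 0 = run to n_steps
  const int n = cap_nF.size();
  if (g_axial_uS.size() != n - 1) stop("coupling vector must have length n-1");

  const double gna = as<double>(membrane["g_na"]);
  const double gk = as<double>(membrane["g_k"]);
  const double gl = as<double>(membrane["g_leak"]);
  const double ena = as<double>(membrane["e_na"]);
  const double ek = as<double>(membrane["e_k"]);
  const double el = as<double>(membrane["e_leak"]);
  const double phi = as<double>(membrane["rate_scale"]);

  // constant tridiagonal left-hand matrix A = C/dt + (L + G_pas)/2
  std::vector<double> lower(n, 0.0), diag(n, 0.0), upper(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double gsum = 0.0;
    if (i > 0) { lower[i] = -0.5 * g_axial_uS[i - 1]; gsum += g_axial_uS[i - 1]; }
    if (i < n - 1) { upper[i] = -0.5 * g_axial_uS[i]; gsum += g_axial_uS[i]; }
    diag[i] = cap_nF[i] / dt + 0.5 * gsum + 0.5 * g_pas_uS[i];
  }
  // Thomas factorisation (constant across steps)
  std::vector<double> dd(n), cp(n, 0.0);
  dd[0] = diag[0];
  cp[0] = upper[0] / dd[0];
  for (int i = 1; i < n; ++i) {
    dd[i] = diag[i] - lower[i] * cp[i - 1];
    if (i < n - 1) cp[i] = upper[i] / dd[i];
  }

  // state: V everywhere, HH gates at node compartments
  std::vector<double> V(n, v_init), m(n, 0.0), h(n, 0.0), nn(n, 0.0);
  {
    Rates r = hh_rates(v_init);
    double m0 = r.am / (r.am + r.bm), h0 = r.ah / (r.ah + r.bh),
           n0 = r.an / (r.an + r.bn);
    for (int i = 0; i < n; ++i) {
      if (is_node[i]) { m[i] = m0; h[i] = h0; nn[i] = n0; }
    }
  }

  const int n_rec = record.size();
  NumericMatrix out(n_steps + 1, n_rec);
  for (int j = 0; j < n_rec; ++j) out(0, j) = V[record[j] - 1];
  NumericVector crossing(n, NA_REAL);
  if (v_init >= threshold) std::fill(crossing.begin(), crossing.end(), 0.0);

  std::vector<double> y(n);
  int steps_done = 0;
  const int stop0 = stop_comp - 1;

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const bool stim_on = (t >= stim_onset_ms && t < stim_onset_ms + stim_dur_ms);
    for (int i = 0; i < n; ++i) {
      double I = 0.0;
      if (is_node[i]) {
        Rates r = hh_rates(V[i]);
        double sm = r.am + r.bm, sh = r.ah + r.bh, sn = r.an + r.bn;
        double minf = r.am / sm, hinf = r.ah / sh, ninf = r.an / sn;
        m[i] = minf + (m[i] - minf) * std::exp(-dt * phi * sm);
        h[i] = hinf + (h[i] - hinf) * std::exp(-dt * phi * sh);
        nn[i] = ninf + (nn[i] - ninf) * std::exp(-dt * phi * sn);
        double iion = gna * m[i] * m[i] * m[i] * h[i] * (V[i] - ena) +
                      gk * nn[i] * nn[i] * nn[i] * nn[i] * (V[i] - ek) +
                      gl * (V[i] - el);            // uA/cm^2, outward +
        I = area_cm2[i] * iion * 1e3;              // -> nA
      }
      double lv = 0.0;
      if (i > 0) lv += g_axial_uS[i - 1] * (V[i] - V[i - 1]);
      if (i < n - 1) lv += g_axial_uS[i] * (V[i] - V[i + 1]);
      double r = cap_nF[i] / dt * V[i] - 0.5 * lv -
                 0.5 * g_pas_uS[i] * (V[i] - e_pas_mV[i]) +
                 0.5 * g_pas_uS[i] * e_pas_mV[i] - I;
      if (stim_on && i == stim_comp - 1) r += stim_amp_nA;
      y[i] = r;
    }
    // solve A v_new = y with the cached factorisation
    for (int i = 1; i < n; ++i) y[i] -= lower[i] * (y[i - 1] / dd[i - 1]);
    y[n - 1] /= dd[n - 1];
    for (int i = n - 2; i >= 0; --i) y[i] = y[i] / dd[i] - cp[i] * y[i + 1];

    const double t_new = t + dt;
    for (int i = 0; i < n; ++i) {
      double v_old = V[i], v_new = y[i];
      if (!std::isfinite(v_new) || std::fabs(v_new) > 500.0) {
        stop("voltage blow-up (|V| > 500 mV) at compartment %d, t = %.4f ms; reduce dt or check parameters",
             i + 1, t_new);
      }
      if (NumericVector::is_na(crossing[i]) && v_old < threshold &&
          v_new >= threshold) {
        crossing[i] = t + dt * (threshold - v_old) / (v_new - v_old);
      }
      V[i] = v_new;
    }
    for (int j = 0; j < n_rec; ++j) out(k + 1, j) = V[record[j] - 1];
    steps_done = k + 1;
    if (stop0 >= 0 && !NumericVector::is_na(crossing[stop0])) break;
  }

  return List::create(_["v"] = out,
                      _["crossing_ms"] = crossing,
                      _["steps_done"] = steps_done);
}
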