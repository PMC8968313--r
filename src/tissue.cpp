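#include <Rcpp.h>
#include "crn_common.h"

using namespace Rcpp;

// Tissue-scale monodomain stepper. The reaction step uses a voltage lookup
// table (linear interpolation on a fine vm grid) for every purely
// V-dependent factor - the standard cardiac-simulation optimization; the
// Ca/Na/K-dependent terms stay exact. Operator splitting per dt:
// reaction (Rush-Larsen / Euler) then explicit diffusion sub-steps.

namespace {

const int NCOL = 30;  // 12 x (inf, rl-factor) + 6 current factors
const double V_TAB_MIN = -120.0;
const double V_TAB_MAX = 80.0;

struct VTable {
  double vmin, dv, inv_dv;
  int n;
  std::vector<double> tab;  // row-major: n rows of NCOL
};

void build_table(VTable &T, double dt, double dv) {
  T.vmin = V_TAB_MIN;
  T.dv = dv;
  T.inv_dv = 1.0 / dv;
  T.n = (int)std::ceil((V_TAB_MAX - V_TAB_MIN) / dv) + 2;
  T.tab.resize((size_t)T.n * NCOL);
  const double rtf = crn::R_GAS * crn::TEMP / crn::FRDY;
  const double sigma = (std::exp(crn::NA_O / 67.3) - 1.0) / 7.0;
  double inf[crn::NGATES_V], tau[crn::NGATES_V];
  for (int i = 0; i < T.n; ++i) {
    double v = T.vmin + i * dv;
    double *row = &T.tab[(size_t)i * NCOL];
    crn::gate_rates(v, inf, tau);
    for (int g = 0; g < crn::NGATES_V; ++g) {
      row[2 * g] = inf[g];
      row[2 * g + 1] = std::exp(-dt / tau[g]);
    }
    row[24] = crn::G_K1 / (1.0 + std::exp(0.07 * (v + 80.0)));
    row[25] = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
    row[26] = crn::G_KR / (1.0 + std::exp((v + 15.0) / 22.4));
    row[27] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf)
                     + 0.0365 * sigma * std::exp(-v / rtf));
    row[28] = std::exp(crn::GAMMA * v / rtf);
    row[29] = std::exp((crn::GAMMA - 1.0) * v / rtf);
  }
}

// tabulated reaction step for one cell; returns total ionic current
inline void step_tab(const VTable &T, double *s, double dt, double istim,
                     const double *sc, double exp_dt_fca, double exp_dt_u) {
  const double v = s[crn::VM];
  double x = (v - T.vmin) * T.inv_dv;
  int i0 = (int)x;
  if (i0 < 0) i0 = 0;
  if (i0 > T.n - 2) i0 = T.n - 2;
  double fr = x - i0;
  const double *a = &T.tab[(size_t)i0 * NCOL];
  const double *b = a + NCOL;
#define LERP(k) (a[k] + fr * (b[k] - a[k]))

  const double rtf = crn::R_GAS * crn::TEMP / crn::FRDY;
  const double ena = rtf * std::log(crn::NA_O / s[crn::NAI]);
  const double ek = rtf * std::log(crn::K_O / s[crn::KI]);
  const double eca = 0.5 * rtf * std::log(crn::CA_O / s[crn::CAI]);

  double ina = sc[crn::S_NA] * crn::G_NA
      * s[crn::M] * s[crn::M] * s[crn::M] * s[crn::H] * s[crn::J] * (v - ena);
  double ik1 = sc[crn::S_K1] * LERP(24) * (v - ek);
  double ito = sc[crn::S_TO] * crn::G_TO
      * s[crn::OA] * s[crn::OA] * s[crn::OA] * s[crn::OI] * (v - ek);
  double ikur = sc[crn::S_KUR] * LERP(25)
      * s[crn::UA] * s[crn::UA] * s[crn::UA] * s[crn::UI] * (v - ek);
  double ikr = sc[crn::S_KR] * LERP(26) * s[crn::XR] * (v - ek);
  double iks = sc[crn::S_KS] * crn::G_KS * s[crn::XS] * s[crn::XS] * (v - ek);
  double ical = sc[crn::S_CAL] * crn::G_CAL
      * s[crn::D] * s[crn::F] * s[crn::FCA] * (v - 65.0);
  double xnk = crn::KM_NA_I / s[crn::NAI];
  double inak = crn::I_NAK_MAX * LERP(27) / (1.0 + xnk * std::sqrt(xnk))
      * crn::K_O / (crn::K_O + crn::KM_K_O);
  double eg = LERP(28), eg1 = LERP(29);
  double nai3 = s[crn::NAI] * s[crn::NAI] * s[crn::NAI];
  double incx = sc[crn::S_NCX] * crn::I_NACA_MAX
      * (eg * nai3 * crn::CA_O
         - eg1 * crn::NA_O * crn::NA_O * crn::NA_O * s[crn::CAI])
      / ((crn::KM_NA * crn::KM_NA * crn::KM_NA
          + crn::NA_O * crn::NA_O * crn::NA_O)
         * (crn::KM_CA + crn::CA_O) * (1.0 + crn::K_SAT * eg1));
  double ibna = crn::G_B_NA * (v - ena);
  double ibca = crn::G_B_CA * (v - eca);
  double ipca = crn::I_PCA_MAX * s[crn::CAI] / (0.0005 + s[crn::CAI]);
  double itot = ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak
      + incx + ibna + ibca;

  // gates
  const int gidx[crn::NGATES_V] = {crn::M, crn::H, crn::J, crn::OA, crn::OI,
                                   crn::UA, crn::UI, crn::XR, crn::XS,
                                   crn::D, crn::F, crn::W};
  for (int g = 0; g < crn::NGATES_V; ++g) {
    double gi = LERP(2 * g), rl = LERP(2 * g + 1);
    s[gidx[g]] = gi + (s[gidx[g]] - gi) * rl;
  }
  double fca_inf = 1.0 / (1.0 + s[crn::CAI] / 0.00035);
  s[crn::FCA] = fca_inf + (s[crn::FCA] - fca_inf) * exp_dt_fca;

  double irel = crn::K_REL * s[crn::U] * s[crn::U] * s[crn::V] * s[crn::W]
      * (s[crn::CAREL] - s[crn::CAI]);
  double fn = 1e3 * (1e-15 * crn::V_REL * irel
                     - (1e-15 / (2.0 * crn::FRDY))
                       * (0.5 * ical * crn::CM - 0.2 * incx * crn::CM));
  double eu = std::exp(-(fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + eu);
  s[crn::U] = u_inf + (s[crn::U] - u_inf) * exp_dt_u;
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  double v_inf = 1.0
      - 1.0 / (1.0 + std::exp(-(fn - 6.835e-14) / 13.67e-16));
  s[crn::V] = v_inf + (s[crn::V] - v_inf) * std::exp(-dt / tau_v);

  double iup = crn::I_UP_MAX / (1.0 + crn::K_UP / s[crn::CAI]);
  double iupleak = crn::I_UP_MAX * s[crn::CAUP] / crn::CA_UP_MAX;
  double itrf = (s[crn::CAUP] - s[crn::CAREL]) / crn::TAU_TR;

  double dnai = crn::CM * (-3.0 * inak - 3.0 * incx - ibna - ina)
      / (crn::V_I * crn::FRDY);
  double dki = crn::CM * (2.0 * inak - ik1 - ito - ikur - ikr - iks)
      / (crn::V_I * crn::FRDY);
  double cai = s[crn::CAI];
  double b1 = crn::CM * (2.0 * incx - ipca - ical - ibca)
      / (2.0 * crn::V_I * crn::FRDY)
      + (crn::V_UP * (iupleak - iup) + irel * crn::V_REL) / crn::V_I;
  double b2 = 1.0
      + crn::TRPN_MAX * crn::KM_TRPN
        / ((cai + crn::KM_TRPN) * (cai + crn::KM_TRPN))
      + crn::CMDN_MAX * crn::KM_CMDN
        / ((cai + crn::KM_CMDN) * (cai + crn::KM_CMDN));
  double carel = s[crn::CAREL];
  double dcarel = (itrf - irel)
      / (1.0 + crn::CSQN_MAX * crn::KM_CSQN
               / ((carel + crn::KM_CSQN) * (carel + crn::KM_CSQN)));

  s[crn::NAI] += dt * dnai;
  s[crn::KI] += dt * dki;
  s[crn::CAI] += dt * b1 / b2;
  s[crn::CAUP] += dt * (iup - iupleak - itrf * crn::V_REL / crn::V_UP);
  s[crn::CAREL] += dt * dcarel;
  s[crn::VM] -= dt * (itot + istim);
#undef LERP
}

}  // namespace

// Run the monodomain simulation over the active (non-ablated) nodes.
//   states: n_active x 21 initial states (row per active node)
//   presets: n_presets x 8 scale sets; node_preset: per-node row index
//     (1-based)
//   lap_*: CSR of the mass-lumped diffusion operator L (dv/dt += L v)
//   stim_*: events with flattened node lists (1-based active indices)
//   record_nodes: 1-based active indices to record
//   t0_ms: absolute time of the first step (for resumed runs)
//   last_act: per-node time of last detected activation (-Inf if none)
// [[Rcpp::export]]
List run_tissue_cpp(NumericMatrix states, NumericMatrix presets,
                    IntegerVector node_preset,
                    IntegerVector lap_ptr, IntegerVector lap_idx,
                    NumericVector lap_val,
                    NumericVector stim_onset, NumericVector stim_duration,
                    NumericVector stim_amplitude, IntegerVector stim_nodes,
                    IntegerVector stim_ptr,
                    double dt, int n_steps, int n_diff_sub,
                    int rec_every, IntegerVector record_nodes,
                    double t0_ms, NumericVector last_act,
                    bool use_tables, double table_dv,
                    double act_threshold, double act_refractory_ms) {
  const int n = states.nrow();
  if (states.ncol() != crn::NSTATE) stop("bad state matrix");
  if ((int)node_preset.size() != n) stop("bad node_preset length");
  if ((int)lap_ptr.size() != n + 1) stop("bad CSR row pointer");

  // copy state into row-major contiguous buffer
  std::vector<double> S((size_t)n * crn::NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < crn::NSTATE; ++k)
      S[(size_t)i * crn::NSTATE + k] = states(i, k);

  const int n_presets = presets.nrow();
  std::vector<double> P((size_t)n_presets * crn::NSCALE);
  for (int p = 0; p < n_presets; ++p)
    for (int k = 0; k < crn::NSCALE; ++k)
      P[(size_t)p * crn::NSCALE + k] = presets(p, k);

  VTable T;
  if (use_tables) build_table(T, dt, table_dv);
  const double exp_dt_fca = std::exp(-dt / crn::TAU_FCA);
  const double exp_dt_u = std::exp(-dt / crn::TAU_U);

  const int n_rec = record_nodes.size();
  const int n_samples = n_steps / rec_every + 1;
  NumericMatrix vm_out(n_rec, n_samples);
  NumericVector t_out(n_samples);

  std::vector<double> vm_prev(n), vdiff(n), vtmp(n), istim(n, 0.0);
  std::vector<double> la(last_act.begin(), last_act.end());
  std::vector<int> act_node, dirty;
  std::vector<double> act_time;
  act_node.reserve(4 * n);
  act_time.reserve(4 * n);
  dirty.reserve(256);

  // raw views of the CSR operator (avoid Rcpp accessors in the hot loop)
  const int *Lp = lap_ptr.begin();
  const int *Li = lap_idx.begin();
  const double *Lx = lap_val.begin();

  const double dt_sub = dt / n_diff_sub;
  const int n_events = stim_onset.size();

  // sample 0: initial condition
  for (int r = 0; r < n_rec; ++r)
    vm_out(r, 0) = S[(size_t)(record_nodes[r] - 1) * crn::NSTATE + crn::VM];
  t_out[0] = t0_ms;

  for (int step = 0; step < n_steps; ++step) {
    const double t = t0_ms + step * dt;
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();

    for (int i = 0; i < n; ++i)
      vm_prev[i] = S[(size_t)i * crn::NSTATE + crn::VM];

    // reaction (with stimulus current folded in)
    // stimulus lookup: mark amplitudes for nodes in active events
    // (n_events is small; direct accumulation per event)
    dirty.clear();
    for (int e = 0; e < n_events; ++e) {
      if (t >= stim_onset[e] && t < stim_onset[e] + stim_duration[e]) {
        for (int q = stim_ptr[e]; q < stim_ptr[e + 1]; ++q) {
          int node = stim_nodes[q] - 1;
          istim[node] += stim_amplitude[e];
          dirty.push_back(node);
        }
      }
    }
    if (use_tables) {
      for (int i = 0; i < n; ++i)
        step_tab(T, &S[(size_t)i * crn::NSTATE], dt, istim[i],
                 &P[(size_t)(node_preset[i] - 1) * crn::NSCALE], exp_dt_fca,
                 exp_dt_u);
    } else {
      for (int i = 0; i < n; ++i)
        crn::step_exact(&S[(size_t)i * crn::NSTATE], dt, istim[i],
                        &P[(size_t)(node_preset[i] - 1) * crn::NSCALE]);
    }
    for (size_t q = 0; q < dirty.size(); ++q) istim[dirty[q]] = 0.0;

    // diffusion sub-steps on vm
    for (int i = 0; i < n; ++i)
      vdiff[i] = S[(size_t)i * crn::NSTATE + crn::VM];
    for (int sub = 0; sub < n_diff_sub; ++sub) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int q = Lp[i]; q < Lp[i + 1]; ++q)
          acc += Lx[q] * vdiff[Li[q]];
        vtmp[i] = vdiff[i] + dt_sub * acc;
      }
      vdiff.swap(vtmp);
    }
    for (int i = 0; i < n; ++i)
      S[(size_t)i * crn::NSTATE + crn::VM] = vdiff[i];

    const double t_new = t0_ms + (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double v = vdiff[i];
      if (!std::isfinite(v) || std::fabs(v) > 200.0)
        stop("numerical blow-up at t = %.3f ms, node %d (vm = %g)",
             t_new, i + 1, v);
      if (vm_prev[i] < act_threshold && v >= act_threshold
          && t_new - la[i] >= act_refractory_ms) {
        la[i] = t_new;
        act_node.push_back(i + 1);
        act_time.push_back(t_new);
      }
    }

    if ((step + 1) % rec_every == 0) {
      int si = (step + 1) / rec_every;
      if (si < n_samples) {
        for (int r = 0; r < n_rec; ++r)
          vm_out(r, si) =
              S[(size_t)(record_nodes[r] - 1) * crn::NSTATE + crn::VM];
        t_out[si] = t_new;
      }
    }
  }

  NumericMatrix final_states(n, crn::NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < crn::NSTATE; ++k)
      final_states(i, k) = S[(size_t)i * crn::NSTATE + k];

  return List::create(
      _["vm"] = vm_out, _["t"] = t_out,
      _["act_node"] = IntegerVector(act_node.begin(), act_node.end()),
      _["act_time"] = NumericVector(act_time.begin(), act_time.end()),
      _["final_states"] = final_states,
      _["last_act"] = NumericVector(la.begin(), la.end()));
}
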