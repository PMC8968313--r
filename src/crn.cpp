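#include <Rcpp.h>
#include "crn_common.h"

using namespace Rcpp;

// Exact vectorized evaluation of all CRN currents over rows of `states`.
// `scales` has either 1 row (broadcast) or one row per state.
// [[Rcpp::export]]
NumericMatrix crn_currents_cpp(NumericMatrix states, NumericMatrix scales) {
  const int n = states.nrow();
  if (states.ncol() != crn::NSTATE)
    stop("state matrix must have %d columns", crn::NSTATE);
  if (scales.ncol() != crn::NSCALE)
    stop("scale matrix must have %d columns", crn::NSCALE);
  const bool bcast = scales.nrow() == 1;
  if (!bcast && scales.nrow() != n)
    stop("scales must have 1 row or one row per state");

  NumericMatrix out(n, 13);
  colnames(out) = CharacterVector::create(
      "na", "k1", "to", "kur", "kr", "ks", "cal", "p_ca", "nak", "ncx",
      "b_na", "b_ca", "total");
  std::vector<double> s(crn::NSTATE), sc(crn::NSCALE);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < crn::NSTATE; ++k) s[k] = states(i, k);
    for (int k = 0; k < crn::NSCALE; ++k) sc[k] = scales(bcast ? 0 : i, k);
    crn::Currents c = crn::currents(s.data(), sc.data());
    out(i, 0) = c.na;  out(i, 1) = c.k1;  out(i, 2) = c.to;
    out(i, 3) = c.kur; out(i, 4) = c.kr;  out(i, 5) = c.ks;
    out(i, 6) = c.cal; out(i, 7) = c.pca; out(i, 8) = c.nak;
    out(i, 9) = c.ncx; out(i, 10) = c.bna; out(i, 11) = c.bca;
    out(i, 12) = c.total;
  }
  return out;
}

// One exact Rush-Larsen / Euler step for each row of `states`.
// [[Rcpp::export]]
NumericMatrix crn_step_cpp(NumericMatrix states, double dt,
                           NumericVector i_stim, NumericMatrix scales) {
  const int n = states.nrow();
  const bool bcast = scales.nrow() == 1;
  if (!bcast && scales.nrow() != n)
    stop("scales must have 1 row or one row per state");
  if (i_stim.size() != n && i_stim.size() != 1)
    stop("i_stim must have length 1 or one entry per state");

  NumericMatrix out = clone(states);
  std::vector<double> s(crn::NSTATE), sc(crn::NSCALE);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < crn::NSTATE; ++k) s[k] = out(i, k);
    for (int k = 0; k < crn::NSCALE; ++k) sc[k] = scales(bcast ? 0 : i, k);
    double ist = i_stim.size() == 1 ? i_stim[0] : i_stim[i];
    crn::step_exact(s.data(), dt, ist, sc.data());
    for (int k = 0; k < crn::NSTATE; ++k) out(i, k) = s[k];
    if (!std::isfinite(s[crn::VM]))
      stop("integration failure: non-finite vm in cell %d after step", i + 1);
  }
  return out;
}

// Single-cell run with a stimulus train. Returns the sampled vm trace and
// the final state. Stimuli: onset times (ms), common duration and amplitude.
// [[Rcpp::export]]
List run_cell_cpp(NumericVector state0, NumericVector scales, double dt,
                  double duration_ms, NumericVector stim_onsets,
                  double stim_duration, double stim_amplitude,
                  double record_interval_ms) {
  if (state0.size() != crn::NSTATE) stop("bad state length");
  if (scales.size() != crn::NSCALE) stop("bad scale length");
  const int n_steps = (int)std::llround(duration_ms / dt);
  const int rec_every = std::max(1, (int)std::llround(record_interval_ms / dt));
  const int n_rec = n_steps / rec_every + 1;

  std::vector<double> s(state0.begin(), state0.end());
  std::vector<double> sc(scales.begin(), scales.end());
  NumericVector vm(n_rec), tt(n_rec);
  vm[0] = s[crn::VM];
  tt[0] = 0.0;
  int ri = 1;
  const int n_stim = stim_onsets.size();
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    double ist = 0.0;
    for (int k = 0; k < n_stim; ++k) {
      if (t >= stim_onsets[k] && t < stim_onsets[k] + stim_duration) {
        ist += stim_amplitude;
      }
    }
    crn::step_exact(s.data(), dt, ist, sc.data());
    if (!std::isfinite(s[crn::VM]) || std::fabs(s[crn::VM]) > 200.0)
      stop("integration failure at t = %.3f ms (vm = %g)", t + dt,
           s[crn::VM]);
    if ((step + 1) % rec_every == 0 && ri < n_rec) {
      vm[ri] = s[crn::VM];
      tt[ri] = (step + 1) * dt;
      ++ri;
    }
  }
  return List::create(_["t"] = tt, _["vm"] = vm,
                      _["state"] = NumericVector(s.begin(), s.end()));
}
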