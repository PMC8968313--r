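#ifndef ATRIALWAVE_CRN_COMMON_H
#define ATRIALWAVE_CRN_COMMON_H

#include <cmath>

// Courtemanche-Ramirez-Nattel (1998) human atrial myocyte model.
// Units: mV, ms, mM, pA/pF. Conductance scale factors multiply the
// named current after its unscaled evaluation; scaled I_CaL / I_NCX
// feed the calcium subsystem so the scaling is physically consistent.

namespace crn {

// state vector layout (per node)
enum StateIdx { VM = 0, M, H, J, OA, OI, UA, UI, XR, XS, D, F, FCA,
                U, V, W, NAI, KI, CAI, CAUP, CAREL, NSTATE };

// scale vector layout
enum ScaleIdx { S_NA = 0, S_TO, S_CAL, S_KUR, S_K1, S_NCX, S_KR, S_KS,
                NSCALE };

// physical constants
const double R_GAS = 8.3143;      // J/(mol K)
const double TEMP = 310.0;        // K
const double FRDY = 96.4867;      // C/mmol
const double CM = 100.0;          // pF
const double V_I = 13668.0;       // um^3
const double V_UP = 1109.52;
const double V_REL = 96.48;
const double NA_O = 140.0;        // mM
const double K_O = 5.4;
const double CA_O = 1.8;

// maximal conductances (nS/pF) and fluxes
const double G_NA = 7.8;
const double G_K1 = 0.09;
const double G_TO = 0.1652;
const double G_KR = 0.029411765;
const double G_KS = 0.12941176;
const double G_CAL = 0.12375;
const double G_B_CA = 0.001131;
const double G_B_NA = 0.0006744375;
const double I_NAK_MAX = 0.59933874;
const double KM_NA_I = 10.0;
const double KM_K_O = 1.5;
const double I_NACA_MAX = 1600.0;
const double GAMMA = 0.35;
const double KM_NA = 87.5;
const double KM_CA = 1.38;
const double K_SAT = 0.1;
const double I_PCA_MAX = 0.275;
const double K_REL = 30.0;
const double I_UP_MAX = 0.005;
const double K_UP = 0.00092;
const double CA_UP_MAX = 15.0;
const double TAU_TR = 180.0;
const double TAU_U = 8.0;
const double TAU_FCA = 2.0;
const double TRPN_MAX = 0.07;
const double KM_TRPN = 0.0005;
const double CMDN_MAX = 0.05;
const double KM_CMDN = 0.00238;
const double CSQN_MAX = 10.0;
const double KM_CSQN = 0.8;
const double KQ10 = 3.0;

const int NGATES_V = 12;  // voltage-gated: m h j oa oi ua ui xr xs d f w

struct Currents {
  double na, k1, to, kur, kr, ks, cal, pca, nak, ncx, bna, bca;
  double total;   // signed sum, pA/pF
  double fn;      // SR release trigger flux
  double irel, iup, iupleak, itr;
};

// voltage-dependent steady states / time constants for the 12 V-gates
inline void gate_rates(double v, double *inf, double *tau) {
  // m
  double am = (std::fabs(v + 47.13) < 1e-10)
      ? 3.2
      : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
  double bm = 0.08 * std::exp(-v / 11.0);
  inf[0] = am / (am + bm);
  tau[0] = 1.0 / (am + bm);
  // h, j
  double ah, bh, aj, bj;
  if (v >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(v + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
    aj = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v))
         * (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * v)
         / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  }
  inf[1] = ah / (ah + bh); tau[1] = 1.0 / (ah + bh);
  inf[2] = aj / (aj + bj); tau[2] = 1.0 / (aj + bj);
  // oa, oi (Ito)
  double aoa = 0.65 / (std::exp(-(v + 10.0) / 8.5)
                       + std::exp(-(v - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
  inf[3] = 1.0 / (1.0 + std::exp(-(v + 20.47) / 17.54));
  tau[3] = 1.0 / ((aoa + boa) * KQ10);
  double aoi = 1.0 / (18.53 + std::exp((v + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(v + 1.26) / 7.44));
  inf[4] = 1.0 / (1.0 + std::exp((v + 43.1) / 5.3));
  tau[4] = 1.0 / ((aoi + boi) * KQ10);
  // ua, ui (IKur)
  double aua = 0.65 / (std::exp(-(v + 10.0) / 8.5)
                       + std::exp(-(v - 30.0) / 59.0));
  double bua = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
  inf[5] = 1.0 / (1.0 + std::exp(-(v + 30.3) / 9.6));
  tau[5] = 1.0 / ((aua + bua) * KQ10);
  double aui = 1.0 / (21.0 + std::exp(-(v - 185.0) / 28.0));
  double bui = std::exp((v - 158.0) / 16.0);
  inf[6] = 1.0 / (1.0 + std::exp((v - 99.45) / 27.48));
  tau[6] = 1.0 / ((aui + bui) * KQ10);
  // xr
  double axr = (std::fabs(v + 14.1) < 1e-10)
      ? 0.0015
      : 0.0003 * (v + 14.1) / (1.0 - std::exp(-(v + 14.1) / 5.0));
  double bxr = (std::fabs(v - 3.3328) < 1e-10)
      ? 3.7836118e-4
      : 7.3898e-5 * (v - 3.3328) / (std::exp((v - 3.3328) / 5.1237) - 1.0);
  inf[7] = 1.0 / (1.0 + std::exp(-(v + 14.1) / 6.5));
  tau[7] = 1.0 / (axr + bxr);
  // xs
  double axs = (std::fabs(v - 19.9) < 1e-10)
      ? 0.00068
      : 4e-5 * (v - 19.9) / (1.0 - std::exp(-(v - 19.9) / 17.0));
  double bxs = (std::fabs(v - 19.9) < 1e-10)
      ? 0.000315
      : 3.5e-5 * (v - 19.9) / (std::exp((v - 19.9) / 9.0) - 1.0);
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(v - 19.9) / 12.7));
  tau[8] = 0.5 / (axs + bxs);
  // d
  inf[9] = 1.0 / (1.0 + std::exp(-(v + 10.0) / 8.0));
  tau[9] = (std::fabs(v + 10.0) < 1e-10)
      ? 4.579 / (1.0 + std::exp(-(v + 10.0) / 6.24))
      : (1.0 - std::exp(-(v + 10.0) / 6.24))
        / (0.035 * (v + 10.0) * (1.0 + std::exp(-(v + 10.0) / 6.24)));
  // f
  inf[10] = 1.0 / (1.0 + std::exp((v + 28.0) / 6.9));
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (v + 10.0) * (v + 10.0))
                   + 0.02);
  // w
  inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(v - 40.0) / 17.0));
  tau[11] = (std::fabs(v - 7.9) < 1e-10)
      ? 6.0 * 0.2 / 1.3
      : 6.0 * (1.0 - std::exp(-(v - 7.9) / 5.0))
        / ((1.0 + 0.3 * std::exp(-(v - 7.9) / 5.0)) * (v - 7.9));
}

// exact ionic currents at a given state, with scale factors applied
inline Currents currents(const double *s, const double *sc) {
  Currents c;
  const double v = s[VM];
  const double rtf = R_GAS * TEMP / FRDY;
  const double ena = rtf * std::log(NA_O / s[NAI]);
  const double ek = rtf * std::log(K_O / s[KI]);
  const double eca = 0.5 * rtf * std::log(CA_O / s[CAI]);

  c.na = sc[S_NA] * G_NA * s[M] * s[M] * s[M] * s[H] * s[J] * (v - ena);
  c.k1 = sc[S_K1] * G_K1 * (v - ek) / (1.0 + std::exp(0.07 * (v + 80.0)));
  c.to = sc[S_TO] * G_TO * s[OA] * s[OA] * s[OA] * s[OI] * (v - ek);
  double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
  c.kur = sc[S_KUR] * gkur * s[UA] * s[UA] * s[UA] * s[UI] * (v - ek);
  c.kr = sc[S_KR] * G_KR * s[XR] * (v - ek)
         / (1.0 + std::exp((v + 15.0) / 22.4));
  c.ks = sc[S_KS] * G_KS * s[XS] * s[XS] * (v - ek);
  c.cal = sc[S_CAL] * G_CAL * s[D] * s[F] * s[FCA] * (v - 65.0);

  double sigma = (std::exp(NA_O / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf)
                       + 0.0365 * sigma * std::exp(-v / rtf));
  c.nak = I_NAK_MAX * fnak
          / (1.0 + std::pow(KM_NA_I / s[NAI], 1.5))
          * K_O / (K_O + KM_K_O);

  double eg = std::exp(GAMMA * v / rtf);
  double eg1 = std::exp((GAMMA - 1.0) * v / rtf);
  double nai3 = s[NAI] * s[NAI] * s[NAI];
  c.ncx = sc[S_NCX] * I_NACA_MAX
          * (eg * nai3 * CA_O - eg1 * NA_O * NA_O * NA_O * s[CAI])
          / ((KM_NA * KM_NA * KM_NA + NA_O * NA_O * NA_O)
             * (KM_CA + CA_O) * (1.0 + K_SAT * eg1));

  c.bna = G_B_NA * (v - ena);
  c.bca = G_B_CA * (v - eca);
  c.pca = I_PCA_MAX * s[CAI] / (0.0005 + s[CAI]);

  c.total = c.na + c.k1 + c.to + c.kur + c.kr + c.ks + c.cal + c.pca
            + c.nak + c.ncx + c.bna + c.bca;

  // SR fluxes (mM/ms) and the release trigger Fn
  c.irel = K_REL * s[U] * s[U] * s[V] * s[W] * (s[CAREL] - s[CAI]);
  c.iup = I_UP_MAX / (1.0 + K_UP / s[CAI]);
  c.iupleak = I_UP_MAX * s[CAUP] / CA_UP_MAX;
  c.itr = (s[CAUP] - s[CAREL]) / TAU_TR;
  c.fn = 1e3 * (1e-15 * V_REL * c.irel
                - (1e-15 / (2.0 * FRDY)) * (0.5 * c.cal * CM
                                            - 0.2 * c.ncx * CM));
  return c;
}

// one exact integration step: Rush-Larsen for gates, forward Euler for
// vm and concentrations. istim in pA/pF (depolarizing negative).
inline void step_exact(double *s, double dt, double istim, const double *sc) {
  Currents c = currents(s, sc);
  double inf[NGATES_V], tau[NGATES_V];
  gate_rates(s[VM], inf, tau);

  const int gidx[NGATES_V] = {M, H, J, OA, OI, UA, UI, XR, XS, D, F, W};
  for (int g = 0; g < NGATES_V; ++g) {
    double e = std::exp(-dt / tau[g]);
    s[gidx[g]] = inf[g] + (s[gidx[g]] - inf[g]) * e;
  }
  // fCa (Ca-dependent) and SR release gates u, v (Fn-dependent)
  double fca_inf = 1.0 / (1.0 + s[CAI] / 0.00035);
  s[FCA] = fca_inf + (s[FCA] - fca_inf) * std::exp(-dt / TAU_FCA);
  double eu = std::exp(-(c.fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + eu);
  s[U] = u_inf + (s[U] - u_inf) * std::exp(-dt / TAU_U);
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(c.fn - 6.835e-14) / 13.67e-16));
  s[V] = v_inf + (s[V] - v_inf) * std::exp(-dt / tau_v);

  // concentrations (Euler)
  double dnai = CM * (-3.0 * c.nak - 3.0 * c.ncx - c.bna - c.na)
                / (V_I * FRDY);
  double dki = CM * (2.0 * c.nak - c.k1 - c.to - c.kur - c.kr - c.ks)
               / (V_I * FRDY);
  double b1 = CM * (2.0 * c.ncx - c.pca - c.cal - c.bca) / (2.0 * V_I * FRDY)
              + (V_UP * (c.iupleak - c.iup) + c.irel * V_REL) / V_I;
  double cai = s[CAI];
  double b2 = 1.0 + TRPN_MAX * KM_TRPN / ((cai + KM_TRPN) * (cai + KM_TRPN))
              + CMDN_MAX * KM_CMDN / ((cai + KM_CMDN) * (cai + KM_CMDN));
  double dcaup = c.iup - c.iupleak - c.itr * V_REL / V_UP;
  double carel = s[CAREL];
  double dcarel = (c.itr - c.irel)
      / (1.0 + CSQN_MAX * KM_CSQN / ((carel + KM_CSQN) * (carel + KM_CSQN)));

  s[NAI] += dt * dnai;
  s[KI] += dt * dki;
  s[CAI] += dt * b1 / b2;
  s[CAUP] += dt * dcaup;
  s[CAREL] += dt * dcarel;
  s[VM] -= dt * (c.total + istim);
}

}  // namespace crn

#endif
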