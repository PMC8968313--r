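---
title: "Modeling atrial fibrillation wave-dynamics with atrialwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling atrial fibrillation wave-dynamics with atrialwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`atrialwave` is an in-silico laboratory for studying how pulmonary vein
isolation (PVI) — complete or with residual conduction gaps — changes
the wave-dynamics of atrial fibrillation (AF). It couples four layers:

1. **Cellular electrophysiology.** The Courtemanche–Ramirez–Nattel (CRN)
   human atrial action potential model: 21 state variables (membrane
   potential, 15 Hodgkin–Huxley-type gates, 5 intracellular/SR calcium,
   sodium and potassium pools). Disease and drug conditions are encoded
   as multiplicative conductance scale sets (`preset_scales()`):
   chronic-AF electrical remodeling (I~Na~ −10%, I~to~ −70%, I~CaL~
   −50%, I~Kur~ −50%, I~K1~ +100%, I~NCX~ +40%), the fibrotic-myocyte
   phenotype (I~K1~ −50%, I~CaL~ −50%, I~Na~ −40% versus normal cells),
   and high-dose (15 µM) flecainide (I~to~ −5%, I~CaL~ −5%, I~Kr~ −30%,
   I~Na~ −45%). Scale sets compose by element-wise product
   (`compose_scales()`), so flecainide acts on top of remodeled tissue
   and, by default, fibrotic cells carry the fibrosis factors composed
   onto the tissue preset (switchable via `fibrosis_composed`).
   Flecainide is a static factor set: the concentration is metadata, and
   rate-dependent (use-dependent) I~Na~ block is deliberately out of
   scope.

2. **Tissue propagation.** A monodomain reaction–diffusion model on a
   triangulated sheet. Diffusion uses a P1 finite-element stiffness
   matrix with mass lumping and a per-triangle conductivity tensor
   `D = d_t I + (d_l − d_t) f fᵀ` built from the local fiber direction,
   so conduction is anisotropic. Ablated nodes are removed from the
   diffusion domain entirely (electrically inert scar with natural
   zero-flux interfaces). We read the convention of clamping ablated
   tissue "to zero" as *no* electrical participation rather than a
   literal 0 mV Dirichlet value, which would act as a permanent
   depolarizing source; removal reproduces the intended permanent
   conduction block.

3. **Virtual intervention geometry.** An idealized left atrium: a flat
   rectangular sheet with four disc-shaped PV sleeve regions in two
   vertically adjacent pairs, each pair encircled by a capsule-shaped
   circumferential lesion. PVI-gap lesion sets leave 2-mm unablated
   corridors at opposite arc positions ("anterior"/"posterior") of each
   ring, four per model by default, each individually addressable for
   gap filling. Focal (disc) lesions support highest-DF-site ablation.

4. **Wave-dynamics analysis.** Dominant frequency (DF) per node from the
   periodogram power spectral density (linear detrend + Hann taper,
   searched in 1–20 Hz, ties to the lower frequency); spatial DF
   variability COV-DF = 100·SD/mean (sample SD); mean AF cycle length
   from pooled activation intervals; the maximal restitution slope
   S~max~ from an exponential fit `APD = A − B·exp(−DI/τ)` evaluated at
   the smallest observed diastolic interval; outcome classification
   (sustained AF / terminated / converted to atrial tachycardia, with
   "defragmentation" = the latter two); and wave-break detection at PVI
   gaps by phase singularities of the voltage delay-embedding phase
   within 5 mm and 50 ms of a corridor transit.

## Why a flat sheet

Patient-specific CT anatomies and electroanatomical maps are not
publicly available, so the geometry module generates a synthetic
stand-in that keeps the *topological* essentials of the experiment: PV
regions that a closed lesion line can isolate, an extra-PV body, and
corridors whose source–sink geometry can break waves. A flat sheet makes
every geometric property controllable and testable (ring closure, gap
arc width, compartment connectivity) at the cost of realism in surface
curvature, wall thickness, and true PV sleeve electrophysiology. The
tissue enclosed between a sleeve and its ring (the antrum) belongs to
the isolated compartment, as it does clinically; `pv_compartments()`
implements that convention.

The fibrosis field is a seeded cluster-growth process (random seed
points grown into discs of randomized radius until the target fraction
is hit), mimicking the patchy fibrosis seen in voltage maps. It
reproduces the *fraction* and *clumpiness* of fibrotic tissue but not
any patient's spatial distribution; map-based placement can be emulated
by interpolating externally supplied map points with
`idw_interpolate()` and thresholding.

## Numerical scheme and its knobs

* **Integration.** Operator splitting per time step: one reaction update
  per cell (Rush–Larsen exponential update for all gates, forward Euler
  for V~m~ and concentrations), then explicit diffusion sub-steps. The
  number of diffusion sub-steps is chosen automatically from the
  Gershgorin bound of the assembled operator with a 0.8 safety factor,
  so explicit stability never depends on the user.
* **Time step.** `dt = 0.02 ms` by default for single-cell work;
  tissue scenarios use `dt = 0.05 ms`, where halving the step changes
  planar conduction velocity by well under 2% (tested).
* **Lookup tables.** The tissue kernel tabulates every purely
  voltage-dependent factor (gate steady states and Rush–Larsen decay
  factors, I~K1~/I~Kur~/I~Kr~ voltage factors, the Na/K-pump and NCX
  exponentials) on a 0.01-mV grid with linear interpolation — the
  standard cardiac-simulation optimization. Concentration-dependent
  terms (Nernst potentials, SR fluxes, the release trigger) remain
  exact. `ionic_currents()` and `step_cell()` always evaluate the exact
  expressions; a dedicated test bounds the tabulated-vs-exact
  discrepancy of whole-tissue traces below 0.1 mV, and the exact kernel
  is verified against an independent scalar transcription of the CRN
  equations to 1e-9 relative error.
* **Activation detection.** Upward crossing of −40 mV with a 50-ms
  refractory period, applied online during integration. APD is APD90 by
  default (the repolarization level is a free parameter; 90% is the
  field's convention).
* **CV calibration.** Conduction velocity is calibrated per condition by
  bisecting the monotone CV-vs-d relation of a planar wave on a uniform
  strip at the scenario's mesh resolution (geometric bisection, since CV
  grows like √d). Discrete conduction block at small d is treated as
  "below target". This mirrors the per-patient CV adjustment that
  personalizes clinical AF models.
* **Degenerate inputs.** Constant traces raise "no dominant frequency" /
  "no action potential" errors rather than returning numbers; nodes with
  too few restitution pairs (fewer than 5) or failed fits are masked,
  not imputed; quiescent regions yield NA cycle lengths.

## Desk-scale study conditions

The clinical-scale experiment (235-µm meshes with 4–5·10⁵ elements,
11,520 ms of induction pacing, 32-s observation, 17–23-s analysis
window) is far beyond a desktop R session, so the package defines a
desk-scale default in `scenario_config()` and keeps every clinical value
reachable through the same fields:

* sheet 50 × 50 mm at 500-µm target edge (≈ 1.2·10⁴ nodes) with 4-mm PV
  ostia. The resolution is pinned by the lesion gaps: in a resolution
  study, 2-mm corridors blocked entirely at 900 µm, conducted only
  marginally at 700 µm, and conducted robustly at 500 µm — so meshes
  coarser than ~500 µm silently turn a gapped PVI into a complete one
  and lose the experiment's central mechanism;
* AF-remodeled tissue with 30% clustered fibrosis (2.5-mm clusters, a
  high persistent-AF burden), fibrosis-scaled conductivity
  (`fibrotic_conduction_factor = 0.4`), and bulk conduction calibrated
  to 0.20 m/s — the low-voltage-area range of heavily remodeled atria.
  Isotropic conduction by default; at these resolutions strong
  anisotropy pushes the transverse coupling toward the discrete
  propagation threshold (`anisotropy_ratio` is available for finer
  meshes);
* induction by the standard rapid-pacing ramp (200 → 120 ms in 10-ms
  steps — the decrement that uniquely matches an 11,520-ms schedule at
  8 beats per level) but with 2 beats per level (2,880 ms) at desk
  scale;
* 4-s observation, analysis window 2.0–3.6 s (the 50–90% fractions of
  the observation; `classify_outcome()` defaults to the 17/32–23/32
  fractions, which reproduce 17–23 s exactly at a 32-s observation).

Episodes that terminate before the analysis window opens are excluded
from the AFCL/DF/S~max~ summaries (fields set to NA), matching the
exclusion rule of the clinical protocol.

**What desk scale can and cannot show.** Idealized flat sheets at these
sizes sit *below the critical mass* for self-sustained fibrillation in
this ionic model: in our domain scans (40–80 mm, 500–900 µm, CV
0.2–0.4 m/s, fibrosis 25–40%, conduction factors 0.05–1) induced
episodes decayed within roughly a second of the last paced beat
whenever the mesh was fine enough to be free of lattice artifacts.
(Coarse 900-µm meshes did sustain multi-second reentry, but that
depended on discretization heterogeneity we do not wish to rely on.)
The desk analysis window is therefore placed over the rapid-drive and
immediate post-drive phase, where local rates are AF-like (cycle
lengths 120–200 ms), wavelets genuinely cross the 2-mm gaps, and
source–sink wave-breaks occur at corridor exits. Tests on these
substrates validate the *operators* (isolation, gap conduction,
spectral and restitution estimators, classification logic) and the
intervention machinery, not the cohort statistics — in particular,
desk-scale defragmentation rates cannot be compared with clinical
rates, because every desk episode self-terminates regardless of
intervention. Larger sheets, finer meshes, and the full 8-beat /
32-s clinical protocol are reachable through the same configuration
fields when more compute is available.

## Design choices on open points

* **AT-versus-AF thresholds.** "Conversion to atrial tachycardia" is
  operationalized as pooled cycle-length CV < 10% together with COV-DF
  < 5% — a spatially organized, spectrally uniform rhythm. Both
  thresholds are exposed in `classify_outcome()`.
* **COV-DF region.** The "high-DF" wording is read as the per-node DFs
  of the analyzed region; a `top_decile = TRUE` variant computes the
  COV over the top 10% of DF values instead.
* **S~max~ source data.** In-AF (dynamic) DI/APD pairs from each node's
  own activation sequence are used for tissue maps; the single-cell
  S1-S2 protocol (`restitution_protocol()`) provides controlled ground
  truth for validating the estimator.
* **Stimulus convention.** Depolarizing stimuli are negative (CRN sign
  convention); the default amplitude is about twice diastolic threshold
  with a 2–3 ms pulse. Amplitudes quoted per unit membrane capacitance
  (pA/pF; the CRN cell has C~m~ = 100 pF).
* **Node indexing.** Node ids are 1-based throughout the R API; VTK
  files use the format's 0-based connectivity.

## Known limitations

Monolayer sheet (no bi-atrial or endo/epi structure, no wall thickness);
fibrosis as an ionic phenotype without microstructural conduction
barriers; static flecainide block; PV sleeves electrically identical to
the body by default (switchable); phase-singularity counting near gaps
rather than full rotor trajectory tracking; and the desk-scale caveats
above.
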