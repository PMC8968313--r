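# Single-cell Courtemanche-Ramirez-Nattel (CRN) atrial myocyte model with
# composable conductance-scaling presets for AF electrical remodeling,
# fibrosis, and flecainide.

.crn_state_names <- c("vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr",
                      "xs", "d", "f", "f_ca", "u", "v", "w",
                      "na_i", "k_i", "ca_i", "ca_up", "ca_rel")

.scale_names <- c("na", "to", "cal", "kur", "k1", "ncx", "kr", "ks")

#' Published resting initial state of the CRN atrial myocyte
#'
#' Returns the standard CRN initial condition: membrane potential (mV),
#' the 15 dimensionless gating variables, and the five intracellular /
#' sarcoplasmic-reticulum concentrations (mM).
#'
#' @return Named numeric vector of length 21 (class `crn_state`).
#' @export
#' @examples
#' s <- crn_initial_state()
#' s["vm"]
crn_initial_state <- function() {
  s <- c(vm = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
         oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
         xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
         f_ca = 7.755e-1, u = 0, v = 1, w = 9.992e-1,
         na_i = 11.17, k_i = 139.0, ca_i = 1.013e-4,
         ca_up = 1.488, ca_rel = 1.488)
  class(s) <- "crn_state"
  s
}

validate_state <- function(state) {
  s <- unclass(state)
  if (length(s) != 21L)
    stop("a CRN state has 21 components, got ", length(s))
  if (is.null(names(s))) names(s) <- .crn_state_names
  gates <- s[2:16]
  if (any(!is.finite(s)))
    stop("invalid cell state: non-finite component '",
         names(s)[which(!is.finite(s))[1]], "'")
  bad <- which(gates < 0 | gates > 1)
  if (length(bad))
    stop("invalid cell state: gate '", names(gates)[bad[1]],
         "' outside [0, 1]")
  conc <- s[17:21]
  bad <- which(conc <= 0)
  if (length(bad))
    stop("invalid cell state: concentration '", names(conc)[bad[1]],
         "' is not positive")
  if (s[["vm"]] <= -100 || s[["vm"]] >= 60)
    stop("invalid cell state: vm outside (-100, 60) mV")
  s
}

new_scales <- function(x) {
  stopifnot(length(x) == 8L)
  x <- setNames(as.numeric(x), .scale_names)
  class(x) <- "current_scales"
  x
}

validate_scales <- function(scales) {
  s <- unclass(scales)
  if (is.null(names(s))) {
    if (length(s) != 8L) stop("a scale set has 8 factors")
    names(s) <- .scale_names
  } else {
    unknown <- setdiff(names(s), .scale_names)
    if (length(unknown))
      stop("unknown current scale(s): ", paste(unknown, collapse = ", "))
    full <- setNames(rep(1, 8L), .scale_names)
    full[names(s)] <- s
    s <- full
  }
  if (any(!is.finite(s)) || any(s < 0))
    stop("scale factors must be finite and >= 0")
  s
}

#' Conductance-scaling presets for AF remodeling, fibrosis, and flecainide
#'
#' Builds the multiplicative conductance/exchanger factor set for one of
#' the modeled tissue conditions. Factors multiply the corresponding CRN
#' current; currents not named by a preset keep a factor of exactly 1.
#'
#' * `baseline`: unmodified CRN myocyte (all factors 1).
#' * `af_remodeling`: chronic-AF electrical remodeling - I_Na x0.90,
#'   I_to x0.30, I_CaL x0.50, I_Kur x0.50, I_K1 x2.00, I_NCX x1.40.
#' * `fibrosis`: fibrotic-myocyte phenotype relative to normal cells -
#'   I_K1 x0.50, I_CaL x0.50, I_Na x0.60.
#' * `flecainide`: high-dose (15 uM) class-Ic block - I_to x0.95,
#'   I_CaL x0.95, I_Kr x0.70, I_Na x0.55. The concentration is metadata
#'   only; no concentration-effect curve or rate-dependent block is
#'   modeled.
#'
#' @param preset One of `"baseline"`, `"af_remodeling"`, `"fibrosis"`,
#'   `"flecainide"`.
#' @return A `current_scales` vector with components
#'   `na, to, cal, kur, k1, ncx, kr, ks`.
#' @seealso [compose_scales()] to stack presets (e.g. flecainide on
#'   AF-remodeled tissue).
#' @export
#' @examples
#' preset_scales("af_remodeling")
preset_scales <- function(preset = c("baseline", "af_remodeling",
                                     "fibrosis", "flecainide")) {
  if (length(preset) == 1L && !preset %in% c("baseline", "af_remodeling",
                                             "fibrosis", "flecainide"))
    stop("unknown preset: '", preset, "'")
  preset <- match.arg(preset)
  s <- setNames(rep(1, 8L), .scale_names)
  switch(preset,
    baseline = NULL,
    af_remodeling = {
      s["na"] <- 0.90; s["to"] <- 0.30; s["cal"] <- 0.50
      s["kur"] <- 0.50; s["k1"] <- 2.00; s["ncx"] <- 1.40
    },
    fibrosis = {
      s["k1"] <- 0.50; s["cal"] <- 0.50; s["na"] <- 0.60
    },
    flecainide = {
      s["to"] <- 0.95; s["cal"] <- 0.95; s["kr"] <- 0.70; s["na"] <- 0.55
    })
  new_scales(s)
}

#' Compose two conductance scale sets
#'
#' Element-wise product of two factor sets; commutative and associative.
#' Used to stack conditions, e.g. flecainide applied to AF-remodeled
#' tissue, or the fibrotic phenotype on top of the tissue preset.
#'
#' @param a,b `current_scales` vectors (or named numeric vectors naming a
#'   subset of `na, to, cal, kur, k1, ncx, kr, ks`).
#' @return A `current_scales` vector.
#' @export
#' @examples
#' compose_scales(preset_scales("af_remodeling"), preset_scales("flecainide"))
compose_scales <- function(a, b) {
  new_scales(validate_scales(a) * validate_scales(b))
}

#' Read conductance scale sets from a YAML configuration
#'
#' The config dialect maps names to either a preset string or a mapping of
#' current names to factors, e.g. `my_drug: {na: 0.7, kr: 0.5}`.
#'
#' @param path Path to a YAML file.
#' @return Named list of `current_scales`.
#' @export
read_scales_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) {
    if (is.character(x) && length(x) == 1L) preset_scales(x)
    else new_scales(validate_scales(unlist(x)))
  })
}

#' Evaluate all CRN ionic currents at a state
#'
#' Computes each membrane current (pA/pF) at the given state with the
#' given scale factors applied, plus their signed sum (`total`). Each
#' scaled current is exactly `factor x` the unscaled CRN current at the
#' same state; pump and background currents carry no scale slot and enter
#' `total` unscaled.
#'
#' @param state A `crn_state` (named length-21 vector) or a matrix with 21
#'   columns for vectorized evaluation.
#' @param scales A `current_scales` vector (default all 1).
#' @return For a single state, a named numeric vector of the 12 currents
#'   and `total`; for a matrix input, a matrix with one row per state.
#' @export
#' @examples
#' ionic_currents(crn_initial_state())["k1"]
ionic_currents <- function(state, scales = preset_scales("baseline")) {
  sc <- matrix(validate_scales(scales), nrow = 1)
  if (is.matrix(state)) {
    out <- crn_currents_cpp(state, sc)
    return(out)
  }
  s <- validate_state(state)
  out <- crn_currents_cpp(matrix(s, nrow = 1), sc)
  setNames(as.numeric(out[1, ]), colnames(out))
}

#' Advance one CRN cell by a single time step
#'
#' Gating variables are updated with the exponential Rush-Larsen rule;
#' membrane potential and concentrations with forward Euler. The update is
#' deterministic: identical inputs give a bit-identical successor state.
#'
#' @param state A `crn_state` vector.
#' @param dt Time step (ms), in (0, 0.1].
#' @param i_stim Stimulus current (pA/pF); depolarizing stimuli are
#'   negative by the CRN sign convention.
#' @param scales A `current_scales` vector.
#' @return The updated `crn_state`.
#' @export
step_cell <- function(state, dt, i_stim = 0,
                      scales = preset_scales("baseline")) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.1)
    stop("dt must be in (0, 0.1] ms")
  s <- validate_state(state)
  sc <- matrix(validate_scales(scales), nrow = 1)
  out <- crn_step_cpp(matrix(s, nrow = 1), dt, i_stim, sc)
  st <- setNames(as.numeric(out[1, ]), .crn_state_names)
  if (any(!is.finite(st)))
    stop("integration failure: non-finite state after step")
  class(st) <- "crn_state"
  st
}

#' Simulate a single cell under a stimulus train
#'
#' Convenience runner over the exact kernel: delivers rectangular current
#' pulses at the given onset times and records the membrane potential.
#'
#' @param scales A `current_scales` vector.
#' @param duration_ms Total simulated time (ms).
#' @param stim_onsets Stimulus onset times (ms).
#' @param stim_duration_ms Pulse width (ms), default 2.
#' @param stim_amplitude Pulse amplitude (pA/pF), default -20
#'   (approximately 2x diastolic threshold).
#' @param dt Time step (ms), default 0.02.
#' @param record_interval_ms Sampling interval of the returned trace (ms).
#' @param state0 Initial state (default the published CRN resting state).
#' @return List with `t` (ms), `vm` (mV), and the final `state`.
#' @export
run_cell <- function(scales = preset_scales("baseline"), duration_ms,
                     stim_onsets = numeric(), stim_duration_ms = 2,
                     stim_amplitude = -20, dt = 0.02,
                     record_interval_ms = 0.5,
                     state0 = crn_initial_state()) {
  s <- validate_state(state0)
  sc <- validate_scales(scales)
  out <- run_cell_cpp(as.numeric(s), as.numeric(sc), dt, duration_ms,
                      as.numeric(stim_onsets), stim_duration_ms,
                      stim_amplitude, record_interval_ms)
  st <- setNames(as.numeric(out$state), .crn_state_names)
  class(st) <- "crn_state"
  list(t = out$t, vm = out$vm, state = st)
}

#' Settle a cell to its quiescent steady state
#'
#' Runs the unstimulated cell for `settle_ms` and returns the final state.
#' Useful as a fixed-point reference and as the diastolic initial
#' condition for restitution protocols.
#'
#' @inheritParams run_cell
#' @param settle_ms Unstimulated settling time (ms), default 10000.
#' @return A `crn_state`.
#' @export
crn_steady_state <- function(scales = preset_scales("baseline"),
                             settle_ms = 10000, dt = 0.02) {
  run_cell(scales, duration_ms = settle_ms, dt = dt,
           record_interval_ms = settle_ms)$state
}

#' Action potential duration at a repolarization fraction
#'
#' APD is measured from the instant of maximal upstroke velocity
#' (maximum dV/dt) to the first subsequent downward crossing of
#' `vm_rest + (1 - repol_fraction) * amplitude`, with linear interpolation
#' between samples. `vm_rest` is the pre-upstroke minimum and `amplitude`
#' the peak-minus-rest excursion of the analyzed beat.
#'
#' @param vm Sampled membrane-potential trace (mV).
#' @param dt Sampling interval of `vm` (ms).
#' @param repol_fraction Repolarization level, default 0.9 (APD90).
#' @param min_amplitude Minimum peak-to-rest excursion (mV) for a
#'   deflection to count as an action potential; default 10.
#' @return APD (ms).
#' @export
measure_apd <- function(vm, dt, repol_fraction = 0.9, min_amplitude = 10) {
  if (repol_fraction <= 0 || repol_fraction >= 1)
    stop("repol_fraction must be in (0, 1)")
  if (length(vm) < 3L || diff(range(vm)) < min_amplitude)
    stop("no action potential found in trace")
  dv <- diff(vm)
  up <- which.max(dv)  # index of max dV/dt (between samples up, up+1)
  rest <- if (up > 1L) min(vm[seq_len(up)]) else min(vm)
  peak_i <- up + which.max(vm[up:length(vm)]) - 1L
  amp <- vm[peak_i] - rest
  if (amp < min_amplitude || dv[up] <= 0)
    stop("no action potential found in trace")
  thr <- rest + (1 - repol_fraction) * amp
  seg <- vm[peak_i:length(vm)]
  cross <- which(seg[-1] < thr & seg[-length(seg)] >= thr)
  if (!length(cross))
    stop("no repolarization crossing found (truncated trace?)")
  i <- peak_i + cross[1L] - 1L  # crossing between samples i and i+1
  frac <- (vm[i] - thr) / (vm[i] - vm[i + 1L])
  t_cross <- (i - 1L + frac) * dt
  t_up <- (up - 1L) * dt
  t_cross - t_up
}

# APDs of every beat in a trace: splits at upstrokes (threshold crossing)
# and measures each beat independently. Returns data.frame(t_up, apd);
# the final beat is dropped if its repolarization is truncated.
apd_sequence <- function(vm, dt, repol_fraction = 0.9, threshold = -40,
                         min_amplitude = 10) {
  up <- which(vm[-1] >= threshold & vm[-length(vm)] < threshold) + 1L
  if (length(up) > 1L)  # enforce a refractory gap of 50 ms
    up <- up[c(TRUE, diff(up) * dt >= 50)]
  res <- lapply(seq_along(up), function(k) {
    i0 <- max(1L, up[k] - ceiling(10 / dt))
    i1 <- if (k < length(up)) up[k + 1L] - 1L else length(vm)
    a <- tryCatch(measure_apd(vm[i0:i1], dt, repol_fraction, min_amplitude),
                  error = function(e) NA_real_)
    c(t_up = (up[k] - 1L) * dt, apd = a)
  })
  out <- as.data.frame(do.call(rbind, res))
  if (!nrow(out)) return(data.frame(t_up = numeric(), apd = numeric()))
  if (nrow(out) && is.na(out$apd[nrow(out)])) out <- out[-nrow(out), ]
  out[!is.na(out$apd), , drop = FALSE]
}

#' S1-S2 restitution protocol on a single cell
#'
#' Paces the cell with `n_s1` S1 beats at cycle length `s1_cl`, then one
#' premature S2 at each coupling interval, and returns the
#' (diastolic interval, APD) pair for every captured S2. The diastolic
#' interval is the S2 coupling interval minus the APD of the last S1 beat.
#' Non-capturing S2 stimuli are omitted.
#'
#' @param scales A `current_scales` vector.
#' @param s1_cl S1 cycle length (ms), >= 100.
#' @param s2_intervals S2 coupling intervals (ms), each >= 100.
#' @param n_s1 Number of S1 conditioning beats (>= 8).
#' @param repol_fraction Repolarization level for APD, default 0.9.
#' @param dt Time step (ms).
#' @param stim_amplitude,stim_duration_ms Stimulus pulse parameters.
#' @return `data.frame(di, apd)`, one row per captured S2.
#' @export
restitution_protocol <- function(scales, s1_cl, s2_intervals, n_s1 = 8,
                                 repol_fraction = 0.9, dt = 0.02,
                                 stim_amplitude = -20,
                                 stim_duration_ms = 2) {
  if (n_s1 < 8) stop("at least 8 S1 beats are required")
  if (s1_cl < 100 || (length(s2_intervals) && any(s2_intervals < 100)))
    stop("cycle lengths and S2 intervals must be >= 100 ms")
  if (!length(s2_intervals))
    return(data.frame(di = numeric(), apd = numeric()))
  rows <- lapply(s2_intervals, function(s2) {
    s1_times <- (seq_len(n_s1) - 1L) * s1_cl
    s2_time <- s1_times[n_s1] + s2
    run <- run_cell(scales, duration_ms = s2_time + 400,
                    stim_onsets = c(s1_times, s2_time),
                    stim_duration_ms = stim_duration_ms,
                    stim_amplitude = stim_amplitude, dt = dt,
                    record_interval_ms = 0.5)
    seq <- apd_sequence(run$vm, 0.5, repol_fraction)
    # need the last S1 beat and a captured S2 beat after it
    s1_beat <- seq[seq$t_up >= s1_times[n_s1] - 5 &
                   seq$t_up < s2_time - 5, , drop = FALSE]
    s2_beat <- seq[seq$t_up >= s2_time - 5, , drop = FALSE]
    if (nrow(s1_beat) != 1L || nrow(s2_beat) < 1L) return(NULL)
    di <- s2 - s1_beat$apd[1L]
    if (di <= 0) return(NULL)
    data.frame(di = di, apd = s2_beat$apd[1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(di = numeric(), apd = numeric()) else out
}

#' @export
print.current_scales <- function(x, ...) {
  cat("CRN conductance scale factors:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.crn_state <- function(x, ...) {
  cat("CRN cell state (vm =", format(x[["vm"]], digits = 5), "mV)\n")
  print(unclass(x), ...)
  invisible(x)
}
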