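# Monodomain reaction-diffusion propagation: anisotropic P1 finite-element
# diffusion on the triangulated sheet (mass-lumped), operator-splitting
# integration (reaction then diffusion per dt), stimulus delivery,
# conduction-velocity measurement and calibration, and the rapid-pacing
# AF induction protocol.

#' Build the anisotropic diffusion operator over non-ablated nodes
#'
#' Assembles the P1 finite-element stiffness matrix with the per-triangle
#' conductivity tensor `D = d_t I + (d_l - d_t) f f'` (f = mean fiber
#' direction) and mass lumping, over the non-ablated nodes only. Ablated
#' nodes carry no state and exchange no current; the tissue boundary and
#' ablated-node interfaces are natural zero-flux boundaries. Rows of the
#' returned operator sum to zero (a spatially uniform voltage diffuses no
#' current).
#'
#' Conductivity follows the fibrosis field: triangles whose vertices are
#' fibrotic carry their diffusion tensor scaled by
#' `fibrotic_conduction_factor` (averaged over the triangle's vertices),
#' so fibrotic patches are slow-conducting as well as ionically
#' remodeled.
#'
#' @param mesh An `atrial_mesh`.
#' @param d_longitudinal Diffusion coefficient along fibers (mm^2/ms).
#' @param d_transverse Coefficient across fibers (mm^2/ms);
#'   `0 < d_transverse <= d_longitudinal`.
#' @param fibrotic_conduction_factor Multiplier on the conductivity of
#'   fibrotic tissue, in (0, 1]; default 0.4.
#' @return A `diffusion_operator`: sparse operator `L` (dv/dt = L v) over
#'   the active nodes, their ids, lumped mass, and an explicit-stability
#'   rate bound.
#' @export
build_diffusion_operator <- function(mesh, d_longitudinal,
                                     d_transverse = d_longitudinal,
                                     fibrotic_conduction_factor = 0.4) {
  if (!(d_longitudinal >= d_transverse && d_transverse > 0))
    stop("require d_longitudinal >= d_transverse > 0")
  active <- which(mesh$tissue != "ablated")
  if (!length(active)) stop("mesh has no non-ablated nodes")
  idx <- integer(nrow(mesh$nodes))
  idx[active] <- seq_along(active)

  tr <- mesh$triangles
  keep <- idx[tr[, 1]] > 0 & idx[tr[, 2]] > 0 & idx[tr[, 3]] > 0
  tr <- tr[keep, , drop = FALSE]
  if (!nrow(tr)) stop("no conducting triangles remain")

  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  area <- abs(det) / 2
  # gradients of the barycentric basis functions
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  c_ <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det

  f <- (mesh$fibers[tr[, 1], , drop = FALSE] +
        mesh$fibers[tr[, 2], , drop = FALSE] +
        mesh$fibers[tr[, 3], , drop = FALSE]) / 3
  nf <- sqrt(rowSums(f^2))
  nf[nf < 1e-12] <- 1
  f <- f / nf
  if (fibrotic_conduction_factor <= 0 || fibrotic_conduction_factor > 1)
    stop("fibrotic_conduction_factor must be in (0, 1]")
  fibn <- as.numeric(mesh$tissue == "fibrotic")
  ftri <- 1 - (1 - fibrotic_conduction_factor) *
    (fibn[tr[, 1]] + fibn[tr[, 2]] + fibn[tr[, 3]]) / 3
  dl <- d_longitudinal * ftri
  dt_ <- d_transverse * ftri
  dxx <- dt_ + (dl - dt_) * f[, 1]^2
  dyy <- dt_ + (dl - dt_) * f[, 2]^2
  dxy <- (dl - dt_) * f[, 1] * f[, 2]

  ii <- jj <- integer(9L * nrow(tr))
  xx <- numeric(9L * nrow(tr))
  k <- 0L
  for (a in 1:3) {
    for (bb in 1:3) {
      val <- area * (dxx * b[, a] * b[, bb] + dyy * c_[, a] * c_[, bb] +
                     dxy * (b[, a] * c_[, bb] + c_[, a] * b[, bb]))
      rng <- k + seq_len(nrow(tr))
      ii[rng] <- idx[tr[, a]]
      jj[rng] <- idx[tr[, bb]]
      xx[rng] <- val
      k <- k + nrow(tr)
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(active), length(active)))
  mass <- as.numeric(Matrix::sparseMatrix(
    i = c(idx[tr[, 1]], idx[tr[, 2]], idx[tr[, 3]]),
    j = rep(1L, 3L * nrow(tr)), x = rep(area / 3, 3),
    dims = c(length(active), 1L)))
  L <- -Matrix::Diagonal(x = 1 / mass) %*% K
  L <- methods::as(L, "CsparseMatrix")
  # explicit-Euler stability bound via Gershgorin rows
  rate <- max(Matrix::rowSums(abs(L)))
  structure(list(L = L, active = active, mass = mass,
                 d_longitudinal = d_longitudinal,
                 d_transverse = d_transverse,
                 fibrotic_conduction_factor = fibrotic_conduction_factor,
                 rate_bound = rate),
            class = "diffusion_operator")
}

#' Create a stimulus event
#'
#' @param nodes Target node ids (mesh numbering).
#' @param onset_ms Onset time (ms), >= 0.
#' @param duration_ms Pulse duration (ms), > 0.
#' @param amplitude Current (pA/pF); depolarizing stimuli are negative.
#' @return A `stim_event` list.
#' @export
stim_event <- function(nodes, onset_ms, duration_ms = 2,
                       amplitude = -20) {
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (onset_ms < 0) stop("onset_ms must be >= 0")
  structure(list(nodes = as.integer(nodes), onset_ms = onset_ms,
                 duration_ms = duration_ms, amplitude = amplitude),
            class = "stim_event")
}

#' Rapid-pacing AF induction protocol
#'
#' Builds the burst-pacing stimulus schedule used to induce AF: a fixed
#' number of beats at each cycle length, stepping from `start_cl_ms` down
#' to `end_cl_ms`. With the defaults (200 to 120 ms in 10-ms steps, eight
#' beats per level) the scheduled span is 8 x (200+190+...+120) =
#' 11,520 ms.
#'
#' @param pacing_nodes Node ids receiving the stimulus.
#' @param start_cl_ms,end_cl_ms First and last cycle length (ms),
#'   `start >= end`.
#' @param decrement_ms Cycle-length step (ms); must divide
#'   `start - end`.
#' @param beats_per_level Beats at each cycle length.
#' @param stim_duration_ms,stim_amplitude Pulse parameters.
#' @param t_start_ms Time of the first beat (ms).
#' @return A `stimulus_schedule` (list of `stim_event`) with attributes
#'   `span_ms` (total scheduled duration) and `cycle_lengths`.
#' @export
#' @examples
#' p <- af_induction_protocol(1)
#' attr(p, "span_ms")  # 11520
af_induction_protocol <- function(pacing_nodes, start_cl_ms = 200,
                                  end_cl_ms = 120, decrement_ms = 10,
                                  beats_per_level = 8,
                                  stim_duration_ms = 2,
                                  stim_amplitude = -20, t_start_ms = 0) {
  if (start_cl_ms < end_cl_ms) stop("start_cl_ms must be >= end_cl_ms")
  if (decrement_ms <= 0) stop("decrement_ms must be > 0")
  if ((start_cl_ms - end_cl_ms) %% decrement_ms != 0)
    stop("start - end must be divisible by decrement_ms")
  cls <- seq(start_cl_ms, end_cl_ms, by = -decrement_ms)
  if (beats_per_level < 1)
    return(structure(list(), class = "stimulus_schedule", span_ms = 0,
                     cycle_lengths = cls))
  intervals <- rep(cls, each = beats_per_level)
  onsets <- t_start_ms + cumsum(c(0, intervals[-length(intervals)]))
  events <- lapply(onsets, function(t0)
    stim_event(pacing_nodes, t0, stim_duration_ms, stim_amplitude))
  structure(events, class = "stimulus_schedule",
            span_ms = beats_per_level * sum(cls), cycle_lengths = cls)
}

#' Total scheduled duration of a stimulus schedule
#' @param schedule A `stimulus_schedule`.
#' @return Span in ms.
#' @export
protocol_span_ms <- function(schedule) attr(schedule, "span_ms")

#' Run a monodomain tissue simulation
#'
#' Operator-splitting integration: a Rush-Larsen/Euler reaction step per
#' cell (stimulus current folded in) followed by explicit diffusion
#' sub-steps chosen automatically to satisfy the stability bound. Normal
#' nodes carry `scales`; fibrotic nodes carry `fibrotic_scales` (by
#' default the fibrosis phenotype composed onto `scales`). Ablated nodes
#' are excluded from the state entirely. Activations (upstroke crossing
#' of -40 mV with a 50-ms refractory) are detected online. Deterministic:
#' identical inputs give identical results.
#'
#' @param mesh An `atrial_mesh` (lesions already applied).
#' @param scales `current_scales` for normal tissue.
#' @param stimuli A `stimulus_schedule`, list of `stim_event`, or NULL.
#' @param duration_ms Simulated duration (ms).
#' @param operator Optional precomputed [build_diffusion_operator()]
#'   result; otherwise built from `d_longitudinal`/`d_transverse`.
#' @param d_longitudinal,d_transverse Diffusion coefficients (mm^2/ms)
#'   when `operator` is NULL.
#' @param fibrotic_conduction_factor Conductivity multiplier of fibrotic
#'   tissue (see [build_diffusion_operator()]).
#' @param fibrotic_scales `current_scales` for fibrotic nodes.
#' @param dt_ms Reaction time step (ms), in (0, 0.1].
#' @param record_interval_ms Trace sampling interval (ms; multiple of
#'   `dt_ms`).
#' @param record_nodes Node ids to record (default: all active nodes).
#' @param init Optional initial state: a `crn_state` applied to every
#'   node, or a matrix with one row per active node (for resumed runs).
#' @param t0_ms Absolute start time (ms) for resumed runs.
#' @param last_act Per-active-node time of the most recent activation
#'   before `t0_ms` (for resumed runs; keeps the refractory logic of the
#'   activation detector consistent across a checkpoint).
#' @param settle_ms Settling time used to derive the per-preset resting
#'   initial state when `init` is NULL.
#' @param use_tables Use the tabulated reaction kernel (default TRUE);
#'   FALSE evaluates the exact expressions (slow, for verification).
#' @param table_dv Voltage grid spacing of the lookup table (mV).
#' @return A `simulation_result`: sampled vm traces (`vm` is
#'   nodes x samples), sample times, detected activations, final full
#'   state, and run metadata.
#' @export
run_tissue <- function(mesh, scales = preset_scales("af_remodeling"),
                       stimuli = NULL, duration_ms,
                       operator = NULL, d_longitudinal = 0.05,
                       d_transverse = d_longitudinal / 5,
                       fibrotic_conduction_factor = 0.4,
                       fibrotic_scales = NULL,
                       dt_ms = 0.02, record_interval_ms = 1,
                       record_nodes = NULL, init = NULL, t0_ms = 0,
                       last_act = NULL, settle_ms = 2000,
                       use_tables = TRUE, table_dv = 0.01) {
  if (dt_ms <= 0 || dt_ms > 0.1) stop("dt_ms must be in (0, 0.1]")
  rec_every <- round(record_interval_ms / dt_ms)
  if (abs(rec_every * dt_ms - record_interval_ms) > 1e-9)
    stop("record_interval_ms must be a multiple of dt_ms")
  if (is.null(operator))
    operator <- build_diffusion_operator(mesh, d_longitudinal,
                                         d_transverse,
                                         fibrotic_conduction_factor)
  active <- operator$active
  n <- length(active)
  idx <- integer(nrow(mesh$nodes))
  idx[active] <- seq_len(n)

  scales <- validate_scales(scales)
  if (is.null(fibrotic_scales))
    fibrotic_scales <- compose_scales(scales, preset_scales("fibrosis"))
  fibrotic_scales <- validate_scales(fibrotic_scales)
  presets <- rbind(scales, fibrotic_scales)
  node_preset <- ifelse(mesh$tissue[active] == "fibrotic", 2L, 1L)

  if (is.null(init)) {
    s_norm <- crn_steady_state(scales, settle_ms = settle_ms, dt = dt_ms)
    s_fib <- if (any(node_preset == 2L))
      crn_steady_state(fibrotic_scales, settle_ms = settle_ms, dt = dt_ms)
    else s_norm
    states <- matrix(0, n, 21)
    states[node_preset == 1L, ] <- matrix(rep(as.numeric(s_norm),
                                              each = sum(node_preset == 1L)),
                                          ncol = 21)
    if (any(node_preset == 2L))
      states[node_preset == 2L, ] <-
        matrix(rep(as.numeric(s_fib), each = sum(node_preset == 2L)),
               ncol = 21)
  } else if (is.matrix(init)) {
    if (nrow(init) != n || ncol(init) != 21)
      stop("init matrix must be n_active x 21")
    states <- init
  } else {
    states <- matrix(rep(as.numeric(validate_state(init)), each = n),
                     ncol = 21)
  }

  # stimulus schedule flattened to event vectors + node list
  if (inherits(stimuli, "stim_event")) stimuli <- list(stimuli)
  if (is.null(stimuli)) stimuli <- list()
  ev_nodes <- integer()
  ev_ptr <- 0L
  onset <- dur <- amp <- numeric(length(stimuli))
  for (k in seq_along(stimuli)) {
    ev <- stimuli[[k]]
    tgt <- idx[ev$nodes]
    tgt <- tgt[tgt > 0]  # stimuli on ablated nodes have no effect
    onset[k] <- ev$onset_ms
    dur[k] <- ev$duration_ms
    amp[k] <- ev$amplitude
    ev_nodes <- c(ev_nodes, tgt)
    ev_ptr <- c(ev_ptr, length(ev_nodes))
  }

  # diffusion sub-steps for explicit stability (safety factor 0.8)
  n_sub <- max(1L, ceiling(dt_ms * operator$rate_bound / (2 * 0.8)))

  if (is.null(record_nodes)) record_nodes <- active
  rec_idx <- idx[record_nodes]
  if (any(rec_idx == 0)) stop("cannot record ablated nodes")

  if (is.null(last_act)) last_act <- rep(-1e9, n)

  Lt <- Matrix::t(operator$L)  # CSC of t(L) = CSR of L
  n_steps <- round(duration_ms / dt_ms)
  out <- run_tissue_cpp(states, presets, node_preset,
                        Lt@p, Lt@i, Lt@x,
                        onset, dur, amp, ev_nodes, as.integer(ev_ptr),
                        dt_ms, n_steps, n_sub, rec_every,
                        rec_idx, t0_ms, last_act,
                        use_tables, table_dv, -40, 50)

  acts <- data.frame(node = active[out$act_node], time_ms = out$act_time)
  structure(list(
    vm = out$vm, times = out$t, record_nodes = record_nodes,
    activations = acts, duration_ms = duration_ms, dt_ms = dt_ms,
    record_interval_ms = record_interval_ms, t0_ms = t0_ms,
    active = active, final_states = out$final_states,
    last_act = out$last_act,
    tissue = mesh$tissue, region = mesh$region,
    meta = list(d_longitudinal = operator$d_longitudinal,
                d_transverse = operator$d_transverse,
                n_diff_sub = n_sub, use_tables = use_tables,
                n_stimuli = length(stimuli))),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result:", length(x$active), "active nodes,",
      sprintf("%.0f ms (dt %.3g ms, sampled every %.3g ms)\n",
              x$duration_ms, x$dt_ms, x$record_interval_ms))
  cat("  activations detected:", nrow(x$activations), "\n")
  invisible(x)
}

#' Activation times of one node
#' @param result A `simulation_result`.
#' @param node Node id.
#' @return Numeric vector of activation times (ms), strictly increasing.
#' @export
activation_times <- function(result, node) {
  result$activations$time_ms[result$activations$node == node]
}

#' Conduction velocity between two probes
#'
#' Distance between the probes divided by the difference of their first
#' activation times, for probes aligned with the propagation direction.
#'
#' @param result A `simulation_result`.
#' @param mesh The `atrial_mesh` of the run.
#' @param probe_a,probe_b Distinct node ids, both activated.
#' @return Conduction velocity (m/s).
#' @export
measure_cv <- function(result, mesh, probe_a, probe_b) {
  if (probe_a == probe_b) stop("probes must be distinct nodes")
  ta <- activation_times(result, probe_a)
  tb <- activation_times(result, probe_b)
  if (!length(ta) || !length(tb))
    stop("no propagation: a probe never activated")
  dt <- abs(tb[1] - ta[1])
  if (dt <= 0) stop("no propagation: probes activated simultaneously")
  dist_mm <- sqrt(sum((mesh$nodes[probe_a, ] - mesh$nodes[probe_b, ])^2))
  dist_mm / dt  # mm/ms == m/s
}

# rectangular strip mesh without PV regions, for planar-wave calibration
strip_mesh <- function(length_mm = 25, width_mm = 8, edge_um = 500) {
  lat <- tri_lattice(length_mm, width_mm, edge_um / 1000)
  n <- nrow(lat$nodes)
  mesh <- structure(list(
    nodes = lat$nodes, triangles = lat$triangles,
    region = ifelse(lat$boundary, "boundary", "la_body"),
    tissue = rep("normal", n),
    fibers = cbind(rep(1, n), rep(0, n)),
    pv_centers = matrix(NA_real_, 4, 2,
                        dimnames = list(paste0("pv", 1:4), c("x", "y"))),
    pv_radius_mm = NA_real_,
    pv_pairs = list(left = c("pv1", "pv2"), right = c("pv3", "pv4")),
    width_mm = length_mm, height_mm = width_mm,
    target_edge_um = edge_um, seed = NA_integer_),
    class = "atrial_mesh")
  es <- edge_length_stats(mesh)
  mesh$edge_mean_um <- es$mean_um
  mesh$edge_sd_um <- es$sd_um
  mesh
}

# planar-wave CV on a strip for a given isotropic-equivalent d pair
planar_cv <- function(d_longitudinal, d_transverse = d_longitudinal,
                      scales = preset_scales("af_remodeling"),
                      edge_um = 500, dt_ms = 0.025, strip = NULL,
                      init_state = NULL) {
  mesh <- if (is.null(strip)) strip_mesh(edge_um = edge_um) else strip
  # a wide, strong edge stimulus so capture survives strong diffusive load
  pace <- which(mesh$nodes[, 1] < 2.0)
  pa <- which.min((mesh$nodes[, 1] - 0.3 * mesh$width_mm)^2 +
                  (mesh$nodes[, 2] - mesh$height_mm / 2)^2)
  pb <- which.min((mesh$nodes[, 1] - 0.7 * mesh$width_mm)^2 +
                  (mesh$nodes[, 2] - mesh$height_mm / 2)^2)
  init <- if (is.null(init_state)) NULL else init_state
  res <- run_tissue(mesh, scales = scales,
                    stimuli = list(stim_event(pace, 1, duration_ms = 3,
                                              amplitude = -40)),
                    duration_ms = mesh$width_mm / 0.1 + 40,
                    d_longitudinal = d_longitudinal,
                    d_transverse = d_transverse, dt_ms = dt_ms,
                    record_interval_ms = max(dt_ms * 40, 1),
                    record_nodes = c(pa, pb), init = init,
                    settle_ms = 1000)
  measure_cv(res, mesh, pa, pb)
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Bisects the (monotone) planar-wave CV-vs-d relation on a uniform strip
#' until the achieved CV is within `tolerance` of the target, mirroring
#' the per-case CV adjustment used to personalize AF models.
#'
#' @param target_cv_m_s Target conduction velocity (m/s), in (0.1, 1.5).
#' @param tolerance Relative tolerance, default 0.05.
#' @param scales Tissue `current_scales` used during calibration.
#' @param edge_um Strip mesh resolution (um).
#' @param dt_ms Time step (ms).
#' @param d_interval Initial bracketing interval for d (mm^2/ms);
#'   expanded if it does not bracket the target.
#' @param max_iter Bisection iteration cap.
#' @return List with `d` (mm^2/ms), `achieved_cv` (m/s), `iterations`,
#'   and the sampled `history`.
#' @export
calibrate_diffusion <- function(target_cv_m_s, tolerance = 0.05,
                                scales = preset_scales("af_remodeling"),
                                edge_um = 500, dt_ms = 0.025,
                                d_interval = c(0.01, 0.3),
                                max_iter = 30) {
  if (target_cv_m_s <= 0.1 || target_cv_m_s >= 1.5)
    stop("target_cv_m_s must be in (0.1, 1.5)")
  strip <- strip_mesh(edge_um = edge_um)
  init <- crn_steady_state(scales, settle_ms = 2000, dt = dt_ms)
  f <- function(d) tryCatch(
    planar_cv(d, d, scales, edge_um, dt_ms, strip, init),
    error = function(e) NA_real_)
  lo <- d_interval[1]
  hi <- d_interval[2]
  cv_lo <- f(lo)
  cv_hi <- f(hi)
  hist <- data.frame(d = c(lo, hi), cv = c(cv_lo, cv_hi))
  # discrete conduction block (NA) at the low end counts as "below target"
  expand <- 0L
  while (!is.na(cv_lo) && cv_lo > target_cv_m_s && expand < 6L) {
    lo <- lo / 3
    cv_lo <- f(lo)
    hist <- rbind(hist, data.frame(d = lo, cv = cv_lo))
    expand <- expand + 1L
  }
  while ((is.na(cv_hi) || cv_hi < target_cv_m_s) && expand < 12L) {
    hi <- hi * 3
    cv_hi <- f(hi)
    hist <- rbind(hist, data.frame(d = hi, cv = cv_hi))
    expand <- expand + 1L
  }
  if ((!is.na(cv_lo) && cv_lo > target_cv_m_s) ||
      is.na(cv_hi) || cv_hi < target_cv_m_s)
    stop("calibration failure: could not bracket the target CV")
  it <- 0L
  d_mid <- NA_real_
  cv_mid <- NA_real_
  repeat {
    it <- it + 1L
    d_mid <- sqrt(lo * hi)  # geometric bisection: CV ~ sqrt(d)
    cv_mid <- f(d_mid)
    hist <- rbind(hist, data.frame(d = d_mid, cv = cv_mid))
    if (!is.na(cv_mid) &&
        (abs(cv_mid - target_cv_m_s) / target_cv_m_s <= tolerance ||
         it >= max_iter)) break
    if (it >= max_iter)
      stop("calibration failure: bisection did not converge")
    if (is.na(cv_mid) || cv_mid < target_cv_m_s) lo <- d_mid else hi <- d_mid
  }
  list(d = d_mid, achieved_cv = cv_mid, iterations = it, history = hist)
}
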