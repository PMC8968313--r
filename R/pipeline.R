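# Experiment orchestration: build -> calibrate -> induce -> intervene ->
# observe -> analyze, for the baseline / CPVI / PVI-gap comparisons and
# the three rescue interventions on ongoing gapped-PVI AF (gap filling,
# highest-DF focal ablation, flecainide).

#' Scenario configuration
#'
#' Bundles every knob of one in-silico AF experiment. The defaults are
#' the desk-scale study conditions: a 50 x 50 mm sheet at 500-um target
#' edge (fine enough for 2-mm lesion gaps to conduct), 30% clustered
#' fibrosis with fibrosis-scaled conductivity, AF-remodeled tissue
#' calibrated to a slow 0.20 m/s, a 2-beat-per-level rapid-pacing
#' induction (200 -> 120 ms, spanning 2,880 ms), 4-s observation with a
#' 2-3.6-s analysis window placed over the rapid-drive and immediate
#' post-drive phase (idealized sheets of this size do not self-sustain
#' fibrillation; see the methods vignette). The clinical-scale protocol
#' (8 beats/level = 11,520 ms of pacing, 32-s observation, 17-23-s
#' window, 235-um meshes) is expressed through the same fields.
#'
#' @param intervention One of `none`, `cpvi`, `pvi_gap`, `fill_gaps`,
#'   `focal_highest_df`, `flecainide`. The last three are rescue
#'   interventions applied at `intervention_time_ms` to an ongoing
#'   gapped-PVI episode.
#' @param width_mm,height_mm,target_edge_um,pv_radius_mm Geometry.
#' @param fibrosis_density,fibrosis_cluster_radius_mm Fibrosis field.
#' @param fibrotic_conduction_factor Conductivity multiplier of fibrotic
#'   tissue (paper-style fibrosis-dependent conductivity), in (0, 1].
#' @param tissue_preset Conductance preset name for non-fibrotic tissue.
#' @param fibrosis_composed Compose the fibrotic phenotype onto the
#'   tissue preset (TRUE) or use it instead of it (FALSE).
#' @param target_cv_m_s,cv_tolerance Conduction-velocity calibration.
#' @param anisotropy_ratio d_longitudinal / d_transverse.
#' @param d Diffusion coefficient (mm^2/ms); NULL calibrates.
#' @param gap_width_mm,gaps_per_model PVI-gap geometry.
#' @param fill_which For `fill_gaps`: `"breaking"` (gaps with observed
#'   wave-breaks), `"all"`, or explicit gap ids.
#' @param focal_radius_mm Radius of the highest-DF focal lesion.
#' @param induction List of [af_induction_protocol()] arguments
#'   (`start_cl_ms`, `end_cl_ms`, `decrement_ms`, `beats_per_level`,
#'   `stim_amplitude`, `stim_duration_ms`).
#' @param observation_ms Observation duration (ms).
#' @param analysis_window_ms `c(start, end)` ms; NULL uses
#'   `observation_ms * c(0.5, 0.9)`.
#' @param intervention_time_ms When rescue interventions act (ms); NULL
#'   uses the later of `observation_ms / 2` and the end of the pacing
#'   ramp.
#' @param dt_ms,record_interval_ms Solver time step and sampling.
#' @param compute_smax,smax_max_nodes Smax map control (fitting is the
#'   slowest metric; nodes are subsampled deterministically beyond the
#'   cap).
#' @param seed Seed driving mesh jitter and fibrosis placement.
#' @param name Scenario label for reports.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(intervention = c("none", "cpvi", "pvi_gap",
                                             "fill_gaps",
                                             "focal_highest_df",
                                             "flecainide"),
                            width_mm = 50, height_mm = 50,
                            target_edge_um = 500, pv_radius_mm = 4,
                            fibrosis_density = 0.30,
                            fibrosis_cluster_radius_mm = 2.5,
                            fibrotic_conduction_factor = 0.4,
                            tissue_preset = "af_remodeling",
                            fibrosis_composed = TRUE,
                            target_cv_m_s = 0.20, cv_tolerance = 0.05,
                            anisotropy_ratio = 1, d = NULL,
                            gap_width_mm = 2, gaps_per_model = 4,
                            fill_which = "breaking",
                            focal_radius_mm = 2.5,
                            induction = list(),
                            observation_ms = 4000,
                            analysis_window_ms = NULL,
                            intervention_time_ms = NULL,
                            dt_ms = 0.05, record_interval_ms = 2,
                            compute_smax = TRUE, smax_max_nodes = 300,
                            seed = 1L, name = NULL) {
  intervention <- match.arg(intervention)
  ind <- utils::modifyList(
    list(start_cl_ms = 200, end_cl_ms = 120, decrement_ms = 10,
         beats_per_level = 2, stim_amplitude = -30,
         stim_duration_ms = 3), induction)
  if (is.null(analysis_window_ms))
    analysis_window_ms <- observation_ms * c(0.5, 0.9)
  if (is.null(intervention_time_ms)) {
    # act on ongoing AF: after the pacing ramp ends, at the earliest
    # half-way through the observation
    span <- ind$beats_per_level *
      sum(seq(ind$start_cl_ms, ind$end_cl_ms, by = -ind$decrement_ms))
    intervention_time_ms <- max(observation_ms / 2, span + 200)
  }
  if (analysis_window_ms[2] > observation_ms ||
      analysis_window_ms[1] < 0)
    stop("analysis window must lie within the observation")
  rescue <- intervention %in% c("fill_gaps", "focal_highest_df",
                                "flecainide")
  if (rescue && intervention_time_ms >= observation_ms)
    stop("intervention time must precede the observation end")
  if (is.null(name)) name <- intervention
  structure(list(
    intervention = intervention, width_mm = width_mm,
    height_mm = height_mm, target_edge_um = target_edge_um,
    pv_radius_mm = pv_radius_mm, fibrosis_density = fibrosis_density,
    fibrosis_cluster_radius_mm = fibrosis_cluster_radius_mm,
    fibrotic_conduction_factor = fibrotic_conduction_factor,
    tissue_preset = tissue_preset, fibrosis_composed = fibrosis_composed,
    target_cv_m_s = target_cv_m_s, cv_tolerance = cv_tolerance,
    anisotropy_ratio = anisotropy_ratio, d = d,
    gap_width_mm = gap_width_mm, gaps_per_model = gaps_per_model,
    fill_which = fill_which, focal_radius_mm = focal_radius_mm,
    induction = ind, observation_ms = observation_ms,
    analysis_window_ms = analysis_window_ms,
    intervention_time_ms = intervention_time_ms, dt_ms = dt_ms,
    record_interval_ms = record_interval_ms,
    compute_smax = compute_smax, smax_max_nodes = smax_max_nodes,
    seed = as.integer(seed), name = name), class = "scenario_config")
}

#' Read a scenario configuration from YAML
#' @param path YAML file whose keys are [scenario_config()] arguments.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("analysis_window_ms"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.numeric(args[[nm]])
  do.call(scenario_config, args)
}

# deterministic pacing site: a small disc in the LA body below the left
# PV pair, clear of any ring band
pacing_site <- function(mesh, radius_mm = 1.5) {
  target <- c(mesh$pv_centers["pv1", 1],
              (mesh$pv_centers["pv1", 2] - mesh$pv_radius_mm - 1.5) / 2)
  d <- sqrt((mesh$nodes[, 1] - target[1])^2 +
            (mesh$nodes[, 2] - target[2])^2)
  nodes <- which(d <= radius_mm & mesh$tissue != "ablated" &
                 mesh$region == "la_body")
  if (!length(nodes)) nodes <- which.min(d)
  nodes
}

# scales pair (normal, fibrotic) for a config, optionally with flecainide
config_scales <- function(config, flecainide = FALSE) {
  tissue <- preset_scales(config$tissue_preset)
  fib <- if (config$fibrosis_composed)
    compose_scales(tissue, preset_scales("fibrosis"))
  else preset_scales("fibrosis")
  if (flecainide) {
    fl <- preset_scales("flecainide")
    tissue <- compose_scales(tissue, fl)
    fib <- compose_scales(fib, fl)
  }
  list(tissue = tissue, fibrotic = fib)
}

# continue a finished run; new_mesh may have additional ablated nodes
# (states of surviving nodes are carried over) and scales may change
resume_tissue <- function(result, mesh, new_mesh = mesh, duration_ms,
                          scales, fibrotic_scales, operator = NULL,
                          stimuli = NULL, dt_ms, record_interval_ms,
                          use_tables = TRUE) {
  if (is.null(operator))
    stop("resume_tissue requires the (new) diffusion operator")
  old_active <- result$active
  keep <- match(operator$active, old_active)
  if (any(is.na(keep)))
    stop("state/mesh mismatch: new active nodes absent from checkpoint")
  init <- result$final_states[keep, , drop = FALSE]
  la <- result$last_act[keep]
  run_tissue(new_mesh, scales = scales, stimuli = stimuli,
             duration_ms = duration_ms, operator = operator,
             fibrotic_scales = fibrotic_scales, dt_ms = dt_ms,
             record_interval_ms = record_interval_ms,
             init = init, t0_ms = result$t0_ms + result$duration_ms,
             last_act = la, use_tables = use_tables)
}

# concatenate a run and its continuation into one simulation_result
splice_results <- function(a, b) {
  if (abs(b$t0_ms - (a$t0_ms + a$duration_ms)) > 1e-6)
    stop("results are not contiguous in time")
  common <- intersect(a$record_nodes, b$record_nodes)
  ra <- match(common, a$record_nodes)
  rb <- match(common, b$record_nodes)
  vm <- cbind(a$vm[ra, , drop = FALSE],
              b$vm[rb, -1, drop = FALSE])  # drop duplicated sample
  structure(list(
    vm = vm, times = c(a$times, b$times[-1]), record_nodes = common,
    activations = rbind(a$activations, b$activations),
    duration_ms = a$duration_ms + b$duration_ms, dt_ms = a$dt_ms,
    record_interval_ms = a$record_interval_ms, t0_ms = a$t0_ms,
    active = b$active, final_states = b$final_states,
    last_act = b$last_act, tissue = b$tissue, region = b$region,
    meta = b$meta), class = "simulation_result")
}

#' Persist a tissue checkpoint
#'
#' Saves the full tissue state (per-node CRN state, activation-detector
#' state, mesh, metadata) so a run can be resumed, possibly under a new
#' intervention.
#'
#' @param result A `simulation_result`.
#' @param mesh The run's `atrial_mesh`.
#' @param path Output file (RDS container of named arrays).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(result, mesh, path) {
  saveRDS(list(final_states = result$final_states,
               last_act = result$last_act, active = result$active,
               t_end_ms = result$t0_ms + result$duration_ms,
               mesh = mesh, meta = result$meta), path)
  invisible(path)
}

#' Resume a persisted checkpoint
#'
#' Continues a simulation from a [save_checkpoint()] file. With
#' `new_intervention = "none"` the continuation is bit-identical to the
#' uninterrupted run; `"flecainide"` recomposes every node's conductance
#' scale set with the flecainide preset (no geometry change).
#' Geometry-modifying rescues (gap filling, focal ablation) carry lesion
#' context and run through [run_scenario()].
#'
#' @param path Checkpoint file from [save_checkpoint()].
#' @param duration_ms How long to continue (ms).
#' @param new_intervention `"none"` or `"flecainide"`.
#' @param scales,fibrotic_scales Scale sets of the original run
#'   (defaults: AF-remodeled tissue with composed fibrotic phenotype).
#' @param dt_ms,record_interval_ms Solver settings (must match the
#'   original run for exact splicing).
#' @param d_longitudinal,d_transverse,fibrotic_conduction_factor
#'   Diffusion settings of the original run.
#' @return A `simulation_result` starting at the checkpoint time.
#' @export
resume_checkpoint <- function(path, duration_ms,
                              new_intervention = c("none", "flecainide"),
                              scales = preset_scales("af_remodeling"),
                              fibrotic_scales = NULL,
                              dt_ms = 0.05, record_interval_ms = 2,
                              d_longitudinal = 0.05,
                              d_transverse = d_longitudinal,
                              fibrotic_conduction_factor = 0.4) {
  new_intervention <- match.arg(new_intervention)
  ck <- readRDS(path)
  mesh <- ck$mesh
  op <- build_diffusion_operator(mesh, d_longitudinal, d_transverse,
                                 fibrotic_conduction_factor)
  if (!identical(op$active, ck$active))
    stop("state/mesh mismatch: checkpoint active set differs")
  scales <- validate_scales(scales)
  if (is.null(fibrotic_scales))
    fibrotic_scales <- compose_scales(scales, preset_scales("fibrosis"))
  if (new_intervention == "flecainide") {
    fl <- preset_scales("flecainide")
    scales <- compose_scales(scales, fl)
    fibrotic_scales <- compose_scales(fibrotic_scales, fl)
  }
  fake <- list(active = ck$active, final_states = ck$final_states,
               last_act = ck$last_act, t0_ms = 0,
               duration_ms = ck$t_end_ms)
  resume_tissue(fake, mesh, mesh, duration_ms, scales, fibrotic_scales,
                operator = op, dt_ms = dt_ms,
                record_interval_ms = record_interval_ms)
}

#' Run one complete scenario
#'
#' Executes build -> calibrate -> (pre-induction ablation) -> induce ->
#' (rescue intervention at the checkpoint) -> observe -> analyze.
#' `none`, `cpvi` and `pvi_gap` apply their lesions before induction;
#' `fill_gaps`, `focal_highest_df` and `flecainide` start as `pvi_gap`,
#' checkpoint the ongoing episode at `intervention_time_ms`, modify the
#' substrate (or, for flecainide, only the conductance scale sets), and
#' continue to the observation end.
#'
#' @param config A `scenario_config`.
#' @param outdir Optional output directory for artifacts (metrics CSV,
#'   VTK maps with DF/Smax scalars, RDS checkpoint, JSON manifest).
#' @param verbose Print stage progress.
#' @return A `scenario_result`: the `outcome_report` plus the mesh,
#'   lesion set, spliced `simulation_result`, calibration info, and
#'   per-gap wave-break table when gaps exist.
#' @export
run_scenario <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  say <- function(...) if (verbose) message(...)
  say("building geometry (seed ", config$seed, ")")
  mesh <- build_idealized_la(config$width_mm, config$height_mm,
                             config$target_edge_um, config$pv_radius_mm,
                             seed = config$seed)
  mesh <- generate_fibrosis(mesh, config$fibrosis_density,
                            config$fibrosis_cluster_radius_mm,
                            seed = config$seed + 1000L)
  sc <- config_scales(config)
  calib <- NULL
  d <- config$d
  if (is.null(d)) {
    say("calibrating conduction velocity to ", config$target_cv_m_s,
        " m/s")
    calib <- calibrate_diffusion(config$target_cv_m_s,
                                 config$cv_tolerance,
                                 scales = sc$tissue,
                                 edge_um = config$target_edge_um,
                                 dt_ms = config$dt_ms)
    d <- calib$d
  }
  d_trans <- d / config$anisotropy_ratio

  rescue <- config$intervention %in% c("fill_gaps", "focal_highest_df",
                                       "flecainide")
  lesions <- switch(config$intervention,
    none = NULL,
    cpvi = make_pvi_lesions(mesh, with_gaps = FALSE),
    make_pvi_lesions(mesh, with_gaps = TRUE,
                     gap_width_mm = config$gap_width_mm,
                     gaps_per_model = config$gaps_per_model))
  mesh1 <- if (is.null(lesions)) mesh else apply_lesions(mesh, lesions)
  op1 <- build_diffusion_operator(mesh1, d, d_trans,
                                  config$fibrotic_conduction_factor)

  pace <- pacing_site(mesh1)
  ind <- config$induction
  protocol <- af_induction_protocol(
    pace, ind$start_cl_ms, ind$end_cl_ms, ind$decrement_ms,
    ind$beats_per_level, ind$stim_duration_ms, ind$stim_amplitude)

  t_int <- if (rescue) config$intervention_time_ms else
    config$observation_ms
  say("simulating 0-", t_int, " ms")
  res1 <- run_tissue(mesh1, scales = sc$tissue, stimuli = protocol,
                     duration_ms = t_int, operator = op1,
                     fibrotic_scales = sc$fibrotic,
                     dt_ms = config$dt_ms,
                     record_interval_ms = config$record_interval_ms)

  mesh2 <- mesh1
  lesions2 <- lesions
  result <- res1
  extra <- list()
  if (rescue) {
    span <- protocol_span_ms(protocol)
    # pre-intervention analysis window: prefer post-pacing activity but
    # keep at least 1.2 s so the DF spectrum has usable resolution
    pre_win <- c(max(res1$t0_ms,
                     min(t_int - 1200, max(span, t_int - 2500))),
                 t_int)
    if (config$intervention == "flecainide") {
      say("applying flecainide at ", t_int, " ms")
      sc2 <- config_scales(config, flecainide = TRUE)
      res2 <- resume_tissue(res1, mesh1, mesh1,
                            config$observation_ms - t_int,
                            sc2$tissue, sc2$fibrotic, operator = op1,
                            dt_ms = config$dt_ms,
                            record_interval_ms = config$record_interval_ms)
    } else if (config$intervention == "fill_gaps") {
      wb <- tryCatch(
        detect_gap_wavebreaks(res1, mesh1, lesions,
                              break_window_ms = 50),
        error = function(e) NULL)
      ids <- if (identical(config$fill_which, "breaking")) {
        if (is.null(wb)) character() else wb$gap_id[wb$break_count > 0]
      } else if (identical(config$fill_which, "all")) {
        gap_ids(lesions)
      } else config$fill_which
      say("filling gap(s): ", paste(ids, collapse = ", "))
      extra$filled_gaps <- ids
      extra$wavebreaks_pre <- wb
      lesions2 <- fill_gaps(lesions, ids)
      mesh2 <- apply_lesions(mesh, lesions2)
      op2 <- build_diffusion_operator(mesh2, d, d_trans,
                                      config$fibrotic_conduction_factor)
      res2 <- resume_tissue(res1, mesh1, mesh2,
                            config$observation_ms - t_int,
                            sc$tissue, sc$fibrotic, operator = op2,
                            dt_ms = config$dt_ms,
                            record_interval_ms = config$record_interval_ms)
    } else {  # focal_highest_df
      dfm_pre <- df_map(res1, pre_win)
      site <- highest_df_site(dfm_pre, mesh1, lesions,
                              exclusion_radius_mm = config$focal_radius_mm)
      say("ablating highest-DF site: node ", site)
      extra$focal_node <- site
      focal <- make_focal_lesion(mesh1, site, config$focal_radius_mm)
      lesions2 <- combine_lesions(lesions, focal)
      mesh2 <- apply_lesions(mesh1, focal)
      op2 <- build_diffusion_operator(mesh2, d, d_trans,
                                      config$fibrotic_conduction_factor)
      res2 <- resume_tissue(res1, mesh1, mesh2,
                            config$observation_ms - t_int,
                            sc$tissue, sc$fibrotic, operator = op2,
                            dt_ms = config$dt_ms,
                            record_interval_ms = config$record_interval_ms)
    }
    result <- splice_results(res1, res2)
  }

  say("analyzing")
  smax_nodes <- NULL
  if (config$compute_smax) {
    rn <- result$record_nodes
    if (length(rn) > config$smax_max_nodes)
      smax_nodes <- rn[round(seq(1, length(rn),
                                 length.out = config$smax_max_nodes))]
  }
  outcome <- classify_outcome(result,
                              observation_ms = config$observation_ms,
                              window_ms = config$analysis_window_ms,
                              mesh = mesh2, lesions = lesions2,
                              compute_smax = config$compute_smax,
                              smax_nodes = smax_nodes)
  wavebreaks <- NULL
  if (!is.null(lesions2) && length(gap_ids(lesions2)) &&
      !outcome$early_termination) {
    wavebreaks <- tryCatch(
      detect_gap_wavebreaks(result, mesh2, lesions2),
      error = function(e) NULL)
  }
  out <- structure(list(
    config = config, outcome = outcome, mesh = mesh2,
    lesions = lesions2, result = result, d = d, calibration = calib,
    wavebreaks = wavebreaks, extra = extra), class = "scenario_result")
  if (!is.null(outdir)) write_scenario_artifacts(out, outdir)
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario '", x$config$name, "' (seed ", x$config$seed, "): ",
      x$outcome$classification, "\n", sep = "")
  print(x$outcome)
  invisible(x)
}

# one metrics row per scenario, Table-1-style
scenario_row <- function(sr) {
  o <- sr$outcome
  data.frame(
    scenario = sr$config$name, intervention = sr$config$intervention,
    seed = sr$config$seed, classification = o$classification,
    defragmented = o$defragmented, mean_afcl_ms = o$mean_afcl_ms,
    mean_df_hz = o$mean_df_hz,
    mean_df_extra_pv_hz = o$mean_df_extra_pv_hz,
    mean_df_intra_pv_hz = o$mean_df_intra_pv_hz,
    cov_df_pct = o$cov_df_pct, mean_smax = o$mean_smax,
    stringsAsFactors = FALSE)
}

#' Run and tabulate a batch of scenarios
#'
#' Runs each configuration (or accepts pre-run `scenario_result`s) and
#' returns one row per scenario with all outcome metrics plus
#' delta-columns against the designated baseline row (Delta mean DF and
#' Delta mean Smax, as in intervention-vs-baseline comparisons). A
#' warning is raised when the scenarios do not share a geometry seed,
#' since paired comparisons expect a shared substrate.
#'
#' @param scenarios List of `scenario_config` or `scenario_result`.
#' @param baseline Index of the baseline scenario (default 1).
#' @param csv Optional path; the table is written as CSV.
#' @param verbose Passed to [run_scenario()].
#' @return data.frame with one row per scenario (stable column order).
#' @export
run_comparison <- function(scenarios, baseline = 1, csv = NULL,
                           verbose = FALSE) {
  if (length(scenarios) < 2) stop("need at least 2 scenarios to compare")
  results <- lapply(scenarios, function(s) {
    if (inherits(s, "scenario_result")) s
    else run_scenario(s, verbose = verbose)
  })
  seeds <- vapply(results, function(r) r$config$seed, integer(1))
  if (length(unique(seeds)) > 1)
    warning("scenarios use different geometry seeds; ",
            "paired comparisons expect a shared substrate")
  tab <- do.call(rbind, lapply(results, scenario_row))
  base <- tab[baseline, ]
  tab$delta_mean_df_hz <- tab$mean_df_hz - base$mean_df_hz
  tab$delta_mean_smax <- tab$mean_smax - base$mean_smax
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  tab
}

# artifacts: CSV row, VTK map, checkpoint, manifest
write_scenario_artifacts <- function(sr, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(scenario_row(sr),
            file.path(outdir, paste0(sr$config$name, "_metrics.csv")),
            row.names = FALSE)
  extras <- list()
  if (!is.null(sr$outcome$df_map)) extras$df_hz <- sr$outcome$df_map$df
  if (!is.null(sr$outcome$smax_map))
    extras$smax <- sr$outcome$smax_map$smax
  extras <- lapply(extras, function(v) {
    v[is.na(v)] <- -1
    v
  })
  write_vtk_mesh(sr$mesh,
                 file.path(outdir, paste0(sr$config$name, "_map.vtk")),
                 extra_scalars = extras)
  save_checkpoint(sr$result, sr$mesh,
                  file.path(outdir,
                            paste0(sr$config$name, "_checkpoint.rds")))
  manifest <- list(name = sr$config$name,
                   intervention = sr$config$intervention,
                   seed = sr$config$seed, d_mm2_ms = sr$d,
                   classification = sr$outcome$classification,
                   package_version =
                     as.character(utils::packageVersion("atrialwave")))
  jsonlite::write_json(manifest,
                       file.path(outdir,
                                 paste0(sr$config$name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
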