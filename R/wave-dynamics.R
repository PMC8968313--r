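# AF wave-dynamics metrics: dominant-frequency (DF) maps from the power
# spectral density of each node's voltage signal, spatial DF variability
# (COV-DF), AF cycle length, restitution-slope (Smax) maps, outcome
# classification, and phase-singularity-based wave-break detection at
# PVI gaps.

#' Dominant frequency of a voltage trace
#'
#' Periodogram power spectral density of the linearly detrended,
#' Hann-tapered window; the DF is the frequency with the highest power in
#' the 1-20 Hz physiological band (ties break toward the lower
#' frequency). The spectral resolution is 1/window-length.
#'
#' @param trace Sampled signal.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param band Search band (Hz), default `c(1, 20)`.
#' @return DF (Hz), with attribute `resolution_hz`.
#' @export
#' @examples
#' t <- seq(0, 6, by = 1/500)[-1]
#' dominant_frequency(sin(2 * pi * 8 * t), 500)
dominant_frequency <- function(trace, sample_rate_hz, band = c(1, 20)) {
  n <- length(trace)
  if (n < sample_rate_hz)
    stop("window must be at least 1 s long")
  if (sd(trace) < 1e-12)
    stop("no dominant frequency: trace has zero variance")
  tt <- seq_len(n)
  x <- trace - (lm.fit(cbind(1, tt), trace)$fitted.values)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))  # Hann
  p <- Mod(fft(x * w))^2
  freqs <- (seq_len(n) - 1) * sample_rate_hz / n
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel)) stop("search band is empty at this resolution")
  df <- freqs[sel[which.max(p[sel])]]  # which.max takes the first = lowest
  attr(df, "resolution_hz") <- sample_rate_hz / n
  df
}

#' Per-node dominant-frequency map
#'
#' Computes the DF of every recorded node's voltage over the analysis
#' window. Nodes with no detected activation inside the window are masked
#' invalid (ablated nodes are never recorded and are invalid by
#' construction).
#'
#' @param result A `simulation_result`.
#' @param window_ms Analysis window `c(start, end)` in ms; the reference
#'   clinical choice is 17-23 s of a 32-s observation.
#' @param band DF search band (Hz).
#' @return A `df_map`: per-mesh-node DF (`NA` where invalid), the valid
#'   mask, window, and spectral resolution.
#' @export
df_map <- function(result, window_ms = c(17000, 23000), band = c(1, 20)) {
  if (window_ms[1] < result$times[1] ||
      window_ms[2] > result$times[length(result$times)] + 1e-9)
    stop("analysis window lies outside the recording")
  sel <- which(result$times >= window_ms[1] & result$times <= window_ms[2])
  fs <- 1000 / result$record_interval_ms
  acts <- result$activations
  active_in_win <- unique(acts$node[acts$time_ms >= window_ms[1] &
                                    acts$time_ms <= window_ms[2]])
  n_mesh <- length(result$tissue)
  df <- rep(NA_real_, n_mesh)
  X <- result$vm[, sel, drop = FALSE]
  nwin <- ncol(X)
  # vectorized periodogram across nodes: detrend + Hann, then mvfft
  tt <- seq_len(nwin)
  basis <- cbind(1, tt)
  proj <- basis %*% solve(crossprod(basis), t(basis))
  Xd <- X - X %*% t(proj)
  w <- 0.5 * (1 - cos(2 * pi * (tt - 1) / (nwin - 1)))
  P <- Mod(stats::mvfft(t(Xd * rep(w, each = nrow(Xd)))))^2
  freqs <- (seq_len(nwin) - 1) * fs / nwin
  fsel <- which(freqs >= band[1] & freqs <= band[2])
  peak <- fsel[max.col(t(P[fsel, , drop = FALSE]), ties.method = "first")]
  node_df <- freqs[peak]
  valid_nodes <- intersect(result$record_nodes, active_in_win)
  pos <- match(valid_nodes, result$record_nodes)
  df[valid_nodes] <- node_df[pos]
  structure(list(df = df, valid = !is.na(df), window_ms = window_ms,
                 resolution_hz = fs / nwin, band = band),
            class = "df_map")
}

#' @export
print.df_map <- function(x, ...) {
  cat(sprintf(
    "df_map: %d valid nodes; window %.0f-%.0f ms; resolution %.3f Hz\n",
    sum(x$valid), x$window_ms[1], x$window_ms[2], x$resolution_hz))
  if (any(x$valid))
    cat(sprintf("  mean DF %.2f Hz (range %.2f-%.2f)\n",
                mean(x$df[x$valid]), min(x$df[x$valid]),
                max(x$df[x$valid])))
  invisible(x)
}

#' Coefficient of variation of the dominant frequency
#'
#' COV-DF = 100 x sample SD / mean of the per-node DFs over the region's
#' valid nodes: an index of the spatial heterogeneity of local activation
#' rates. `top_decile = TRUE` restricts to the highest-DF decile of the
#' region.
#'
#' @param dfmap A `df_map`.
#' @param region_mask Node ids (or logical mask) delimiting the region;
#'   default all nodes.
#' @param top_decile Use only the top 10 percent of DF values.
#' @return COV-DF in percent.
#' @export
cov_df <- function(dfmap, region_mask = NULL, top_decile = FALSE) {
  v <- dfmap$df
  if (!is.null(region_mask)) {
    keep <- rep(FALSE, length(v))
    keep[region_mask] <- TRUE
    v[!keep] <- NA
  }
  v <- v[!is.na(v)]
  if (top_decile && length(v) >= 10)
    v <- v[v >= stats::quantile(v, 0.9)]
  if (length(v) < 2)
    stop("COV-DF needs at least 2 valid nodes in the region")
  100 * sd(v) / mean(v)
}

#' Mean AF cycle length over a region
#'
#' Mean of consecutive activation-time differences pooled over the
#' region's nodes within the window.
#'
#' @param result A `simulation_result`.
#' @param region_mask Node ids; default all non-ablated nodes.
#' @param window_ms Analysis window `c(start, end)` (ms); default the
#'   whole recording.
#' @return Mean AFCL (ms), or `NA` (with attribute `reason`) when fewer
#'   than two activations exist on every node.
#' @export
mean_afcl <- function(result, region_mask = NULL, window_ms = NULL) {
  acts <- result$activations
  if (is.null(window_ms))
    window_ms <- c(result$t0_ms, result$t0_ms + result$duration_ms)
  acts <- acts[acts$time_ms >= window_ms[1] & acts$time_ms <= window_ms[2], ]
  if (!is.null(region_mask)) acts <- acts[acts$node %in% region_mask, ]
  ivals <- unlist(lapply(split(acts$time_ms, acts$node), function(tt) {
    if (length(tt) >= 2) diff(sort(tt)) else numeric()
  }), use.names = FALSE)
  if (!length(ivals)) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient activations"
    return(out)
  }
  mean(ivals)
}

#' Fit an exponential APD restitution curve and its maximal slope
#'
#' Fits `APD = A - B exp(-DI / tau)` by nonlinear least squares and
#' returns Smax = `(B / tau) exp(-DI_min / tau)`: the slope at the
#' smallest observed diastolic interval, where the restitution curve is
#' steepest. Slopes above 1 promote alternans and wave-break.
#'
#' @param di Diastolic intervals (ms).
#' @param apd Action potential durations (ms).
#' @return List with `smax`, coefficients `A`, `B`, `tau`, and `di_min`;
#'   or NULL if the fit fails.
#' @export
fit_restitution <- function(di, apd) {
  if (length(di) < 3 || length(di) != length(apd)) return(NULL)
  if (sd(apd) < 1e-9)
    return(list(smax = 0, A = mean(apd), B = 0, tau = NA_real_,
                di_min = min(di)))
  starts <- list(
    list(A = max(apd), B = max(1, diff(range(apd))),
         tau = max(20, mean(di) / 2)),
    list(A = max(apd) + 10, B = max(5, 2 * diff(range(apd))),
         tau = max(10, diff(range(di)) / 3)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(apd ~ A - B * exp(-di / tau), start = st,
                        lower = c(A = 0, B = 0, tau = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  di_min <- min(di)
  list(smax = unname(cf["B"] / cf["tau"] * exp(-di_min / cf["tau"])),
       A = unname(cf["A"]), B = unname(cf["B"]), tau = unname(cf["tau"]),
       di_min = di_min)
}

# per-node (DI, APD) pairs from the in-AF activation sequence of a
# recorded trace: APD90 per beat, DI = activation interval - previous APD
node_restitution_pairs <- function(vm, dt_sample, t_offset = 0,
                                   window_ms = NULL,
                                   repol_fraction = 0.9) {
  seq <- apd_sequence(vm, dt_sample, repol_fraction)
  if (nrow(seq) < 2) return(data.frame(di = numeric(), apd = numeric()))
  seq$t_up <- seq$t_up + t_offset
  if (!is.null(window_ms))
    seq <- seq[seq$t_up >= window_ms[1] & seq$t_up <= window_ms[2], ,
               drop = FALSE]
  if (nrow(seq) < 2) return(data.frame(di = numeric(), apd = numeric()))
  ival <- diff(seq$t_up)
  di <- ival - seq$apd[-nrow(seq)]
  keep <- di > 0
  data.frame(di = di[keep], apd = seq$apd[-1][keep])
}

#' Per-node restitution-slope (Smax) map
#'
#' For every recorded node, collects consecutive (DI, APD) pairs from the
#' activation sequence inside the window (DI = activation interval minus
#' the preceding APD90), fits the exponential restitution curve, and maps
#' the slope at the smallest observed DI. Nodes with fewer than
#' `min_pairs` pairs, or with a failed fit, are masked.
#'
#' @param result A `simulation_result`.
#' @param window_ms Analysis window (ms).
#' @param min_pairs Minimum number of (DI, APD) pairs, default 5.
#' @param nodes Node ids to analyze (default: all recorded nodes).
#' @return A `smax_map`: per-node Smax (`NA` masked) and the valid mask.
#' @export
smax_map <- function(result, window_ms = NULL, min_pairs = 5,
                     nodes = NULL) {
  if (is.null(nodes)) nodes <- result$record_nodes
  n_mesh <- length(result$tissue)
  sm <- rep(NA_real_, n_mesh)
  dt_s <- result$record_interval_ms
  for (nd in nodes) {
    r <- match(nd, result$record_nodes)
    if (is.na(r)) next
    pr <- node_restitution_pairs(result$vm[r, ], dt_s,
                                 t_offset = result$times[1],
                                 window_ms = window_ms)
    if (nrow(pr) < min_pairs) next
    ft <- fit_restitution(pr$di, pr$apd)
    if (!is.null(ft) && is.finite(ft$smax)) sm[nd] <- ft$smax
  }
  structure(list(smax = sm, valid = !is.na(sm), window_ms = window_ms,
                 min_pairs = min_pairs), class = "smax_map")
}

#' Classify the outcome of an AF episode
#'
#' Mutually exclusive, exhaustive classification at the end of the
#' observation:
#' * `terminated` - no activation on any non-ablated node during the
#'   final 2,000 ms;
#' * `converted_to_at` - still active but regular: pooled cycle-length
#'   coefficient of variation below `at_cl_cv` and COV-DF below
#'   `at_cov_df` (a spatially organized, spectrally uniform tachycardia);
#' * `sustained_af` - otherwise.
#'
#' AF defragmentation = termination or conversion to AT. Episodes that
#' terminate before the analysis window opens are excluded from the
#' AFCL/DF/Smax summaries (fields set NA).
#'
#' @param result A `simulation_result`.
#' @param observation_ms Observation end (ms); default the recording end.
#' @param window_ms Metrics window; default scales the 17/32-23/32
#'   fractions of the observation.
#' @param mesh Optional `atrial_mesh` for regional (intra/extra-PV)
#'   metrics.
#' @param lesions Optional `lesion_set` for the intra-PV compartment.
#' @param at_cl_cv Cycle-length regularity threshold (fraction), 0.10.
#' @param at_cov_df Spatial DF-uniformity threshold (percent), 5.
#' @param compute_smax Compute the Smax map (slowest metric)?
#' @param smax_nodes Optional node subset for the Smax map.
#' @return An `outcome_report`.
#' @export
classify_outcome <- function(result, observation_ms = NULL,
                             window_ms = NULL, mesh = NULL,
                             lesions = NULL, at_cl_cv = 0.10,
                             at_cov_df = 5, compute_smax = TRUE,
                             smax_nodes = NULL) {
  if (is.null(observation_ms))
    observation_ms <- result$t0_ms + result$duration_ms
  if (is.null(window_ms))
    window_ms <- observation_ms * c(17, 23) / 32
  acts <- result$activations
  last_win <- acts$time_ms > observation_ms - 2000 &
              acts$time_ms <= observation_ms
  terminated <- !any(last_win)
  # terminated before the analysis window opens -> metrics not applicable
  early_term <- terminated && !any(acts$time_ms > window_ms[1])

  cls <- "sustained_af"
  mean_df <- mean_df_extra <- mean_df_intra <- covdf <- NA_real_
  afcl <- NA_real_
  mean_smax <- NA_real_
  dfm <- NULL
  smm <- NULL
  comp <- if (!is.null(mesh)) pv_compartments(mesh, lesions) else NULL

  if (!early_term) {
    dfm <- tryCatch(df_map(result, window_ms), error = function(e) NULL)
    if (!is.null(dfm) && any(dfm$valid)) {
      mean_df <- mean(dfm$df[dfm$valid])
      covdf <- tryCatch(cov_df(dfm), error = function(e) NA_real_)
      if (!is.null(comp)) {
        vi <- dfm$df[intersect(comp$intra, which(dfm$valid))]
        ve <- dfm$df[intersect(comp$extra, which(dfm$valid))]
        if (length(vi)) mean_df_intra <- mean(vi)
        if (length(ve)) mean_df_extra <- mean(ve)
      }
    }
    afcl <- mean_afcl(result, window_ms = window_ms)
    if (compute_smax) {
      smm <- smax_map(result, window_ms = window_ms, nodes = smax_nodes)
      if (any(smm$valid)) mean_smax <- mean(smm$smax[smm$valid])
    }
  }

  if (terminated) {
    cls <- "terminated"
  } else {
    win_acts <- acts[acts$time_ms >= window_ms[1] &
                     acts$time_ms <= observation_ms, ]
    ivals <- unlist(lapply(split(win_acts$time_ms, win_acts$node),
                           function(tt) if (length(tt) >= 2) diff(sort(tt))
                                        else numeric()),
                    use.names = FALSE)
    cl_cv <- if (length(ivals) >= 2) sd(ivals) / mean(ivals) else Inf
    if (is.finite(cl_cv) && cl_cv < at_cl_cv &&
        !is.na(covdf) && covdf < at_cov_df)
      cls <- "converted_to_at"
  }

  structure(list(
    classification = cls,
    defragmented = cls %in% c("terminated", "converted_to_at"),
    mean_afcl_ms = if (early_term) NA_real_ else afcl,
    mean_df_hz = mean_df, mean_df_extra_pv_hz = mean_df_extra,
    mean_df_intra_pv_hz = mean_df_intra, cov_df_pct = covdf,
    mean_smax = mean_smax, window_ms = window_ms,
    observation_ms = observation_ms, early_termination = early_term,
    df_map = dfm, smax_map = smm), class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("outcome:", x$classification,
      if (x$defragmented) "(defragmented)" else "", "\n")
  cat(sprintf("  mean AFCL %.1f ms | mean DF %.2f Hz | COV-DF %.1f%% | mean Smax %.3f\n",
              x$mean_afcl_ms, x$mean_df_hz, x$cov_df_pct, x$mean_smax))
  invisible(x)
}

#' Instantaneous phase map by delayed-coordinate embedding
#'
#' Phase of each recorded node at the requested sample times, from the
#' (v(t) - v*, v(t + tau) - v*) embedding with per-node mean offset v*.
#'
#' @param result A `simulation_result`.
#' @param times_ms Sample times (ms; snapped to the recording grid).
#' @param tau_ms Embedding delay (ms), default 10.
#' @return Matrix nodes x times of phases in (-pi, pi].
#' @export
phase_map <- function(result, times_ms, tau_ms = 10) {
  lag <- round(tau_ms / result$record_interval_ms)
  idx <- pmin(pmax(round((times_ms - result$times[1]) /
                         result$record_interval_ms) + 1, 1),
              ncol(result$vm) - lag)
  vstar <- rowMeans(result$vm)
  atan2(result$vm[, idx + lag, drop = FALSE] - vstar,
        result$vm[, idx, drop = FALSE] - vstar)
}

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

# triangles whose phase winding is +-2pi at a given phase snapshot;
# `tri` indexes rows of `phase` (recorded-node numbering)
singular_triangles <- function(phase_col, tri) {
  d1 <- wrap_pi(phase_col[tri[, 2]] - phase_col[tri[, 1]])
  d2 <- wrap_pi(phase_col[tri[, 3]] - phase_col[tri[, 2]])
  d3 <- wrap_pi(phase_col[tri[, 1]] - phase_col[tri[, 3]])
  wind <- d1 + d2 + d3
  which(abs(wind) > 1.5 * pi)
}

#' Detect phase singularities near a location
#'
#' Counts elementary mesh triangles whose phase winding is +-2pi
#' (phase-space method on the voltage-delay embedding) within a radius of
#' a point, at each requested time.
#'
#' @param result A `simulation_result` recording the relevant nodes.
#' @param mesh The run's `atrial_mesh`.
#' @param times_ms Times to inspect (ms).
#' @param center Optional c(x, y) (mm); NULL inspects the whole sheet.
#' @param radius_mm Search radius around `center`.
#' @param tau_ms Embedding delay (ms).
#' @return data.frame(time_ms, n_singularities).
#' @export
phase_singularities <- function(result, mesh, times_ms, center = NULL,
                                radius_mm = 5, tau_ms = 10) {
  rec <- result$record_nodes
  rmap <- match(seq_len(nrow(mesh$nodes)), rec)  # mesh node -> row of vm
  tri <- mesh$triangles
  ok <- !is.na(rmap[tri[, 1]]) & !is.na(rmap[tri[, 2]]) &
        !is.na(rmap[tri[, 3]])
  tri <- tri[ok, , drop = FALSE]
  if (!is.null(center)) {
    cx <- (mesh$nodes[tri[, 1], 1] + mesh$nodes[tri[, 2], 1] +
           mesh$nodes[tri[, 3], 1]) / 3
    cy <- (mesh$nodes[tri[, 1], 2] + mesh$nodes[tri[, 2], 2] +
           mesh$nodes[tri[, 3], 2]) / 3
    tri <- tri[(cx - center[1])^2 + (cy - center[2])^2 <= radius_mm^2, ,
               drop = FALSE]
  }
  tri_r <- matrix(rmap[tri], ncol = 3)
  ph <- phase_map(result, times_ms, tau_ms)
  data.frame(
    time_ms = times_ms,
    n_singularities = vapply(seq_along(times_ms), function(k)
      length(singular_triangles(ph[, k], tri_r)), integer(1)))
}

#' Wave-break detection at PVI gaps
#'
#' For each conduction gap: wavefront transits are read from the
#' activation sequence of the gap corridor; the transit direction
#' (PV-to-LA or LA-to-PV) comes from the activation-time order of the
#' inner (PV-side) versus outer (LA-side) neighborhoods. A wave-break is
#' scored when a phase singularity appears within `radius_mm` of the gap
#' exit within `break_window_ms` after the transit - the signature of
#' wavefront fractionation by source-sink mismatch at the corridor exit.
#'
#' @param result A `simulation_result` recording the gap neighborhoods.
#' @param mesh The run's `atrial_mesh`.
#' @param lesions A `lesion_set` with at least one unfilled gap.
#' @param radius_mm Neighborhood radius (mm), default 5.
#' @param break_window_ms Post-transit window (ms), default 50.
#' @param tau_ms Phase-embedding delay (ms).
#' @return data.frame(gap_id, transits, pv_to_la, la_to_pv, break_count).
#' @export
detect_gap_wavebreaks <- function(result, mesh, lesions, radius_mm = 5,
                                  break_window_ms = 50, tau_ms = 10) {
  ids <- gap_ids(lesions)
  if (!length(ids)) stop("lesion set has no unfilled gaps")
  acts <- result$activations
  out <- lapply(ids, function(id) {
    geo <- gap_geometry(lesions, id)
    corridor <- gap_corridor_nodes(mesh, lesions, id)
    corridor <- corridor[mesh$tissue[corridor] != "ablated"]
    d <- sqrt((mesh$nodes[, 1] - geo$center[1])^2 +
              (mesh$nodes[, 2] - geo$center[2])^2)
    near <- which(d <= radius_mm & mesh$tissue != "ablated")
    # PV side: inside the ring; LA side: outside
    ctrs <- mesh$pv_centers[geo$ring$pair, , drop = FALSE]
    ord <- order(ctrs[, 2])
    dy <- pmin(pmax(mesh$nodes[, 2], ctrs[ord[1], 2]), ctrs[ord[2], 2])
    dseg <- sqrt((mesh$nodes[, 1] - ctrs[ord[1], 1])^2 +
                 (mesh$nodes[, 2] - dy)^2)
    inner <- setdiff(near[dseg[near] < geo$ring$radius -
                          geo$ring$width_mm / 2], corridor)
    outer <- setdiff(near[dseg[near] > geo$ring$radius +
                          geo$ring$width_mm / 2], corridor)
    tmid <- sort(acts$time_ms[acts$node %in% corridor])
    # cluster corridor activations into transits (one per wavefront)
    if (length(tmid))
      tmid <- tmid[c(TRUE, diff(tmid) > 40)]
    n_p2l <- n_l2p <- n_break <- 0L
    for (tt in tmid) {
      t_in <- acts$time_ms[acts$node %in% inner &
                           abs(acts$time_ms - tt) <= 40]
      t_out <- acts$time_ms[acts$node %in% outer &
                            abs(acts$time_ms - tt) <= 40]
      if (!length(t_in) || !length(t_out)) next
      if (min(t_in) < min(t_out)) n_p2l <- n_p2l + 1L
      else n_l2p <- n_l2p + 1L
      t_chk <- seq(tt, min(tt + break_window_ms,
                           result$times[length(result$times)] -
                           tau_ms - result$record_interval_ms),
                   by = 5)
      ps <- phase_singularities(result, mesh, t_chk, center = geo$center,
                                radius_mm = radius_mm, tau_ms = tau_ms)
      if (any(ps$n_singularities > 0)) n_break <- n_break + 1L
    }
    data.frame(gap_id = id, transits = n_p2l + n_l2p,
               pv_to_la = n_p2l, la_to_pv = n_l2p, break_count = n_break)
  })
  do.call(rbind, out)
}

#' Highest-DF site outside exclusion zones
#'
#' Returns the valid node with the maximal DF whose distance to every gap
#' corridor exceeds `exclusion_radius_mm` ("ablation of the highest DF
#' site without touching the PVI gaps"). Ties break toward the lowest
#' node id.
#'
#' @param dfmap A `df_map`.
#' @param mesh An `atrial_mesh`.
#' @param lesions Optional `lesion_set` whose gap corridors are excluded.
#' @param exclusion_radius_mm Exclusion radius (mm), default 3.
#' @return Node id of the selected site.
#' @export
highest_df_site <- function(dfmap, mesh, lesions = NULL,
                            exclusion_radius_mm = 3) {
  cand <- which(dfmap$valid)
  if (!is.null(lesions)) {
    for (id in gap_ids(lesions)) {
      cn <- gap_corridor_nodes(mesh, lesions, id)
      if (!length(cn)) next
      d2 <- outer(mesh$nodes[cand, 1], mesh$nodes[cn, 1], "-")^2 +
            outer(mesh$nodes[cand, 2], mesh$nodes[cn, 2], "-")^2
      cand <- cand[sqrt(apply(d2, 1, min)) > exclusion_radius_mm]
      if (!length(cand)) break
    }
  }
  if (!length(cand))
    stop("no valid node outside the exclusion zones")
  best <- cand[dfmap$df[cand] == max(dfmap$df[cand])]
  min(best)
}
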