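# DF / COV-DF / AFCL / Smax metrics, outcome classification, phase
# singularities, and highest-DF site selection, exercised on synthetic
# constructions with known answers.

test_that("dominant frequency recovers pure tones and AP trains", {
  fs <- 500
  t <- seq(1 / fs, 6, by = 1 / fs)
  df <- dominant_frequency(sin(2 * pi * 8 * t), fs)
  expect_lt(abs(df - 8), 1 / 6 + 1e-9)
  # periodic AP-like trains across the physiological range
  for (cl in c(100, 125, 150, 200, 250)) {
    vm <- ap_train(6000, cl, dt_s = 2)
    got <- dominant_frequency(vm, 500)
    expect_lt(abs(got - 1000 / cl), attr(got, "resolution_hz") + 1e-9)
  }
  expect_error(dominant_frequency(rep(1, 3000), fs), "zero variance")
  expect_error(dominant_frequency(sin(1:100), fs), "1 s")
})

test_that("df_map masks silent nodes and keeps the partition", {
  # 3 nodes: 8 Hz, 5 Hz, silent
  tr <- rbind(ap_train(6000, 125), ap_train(6000, 200),
              rep(-80, length(ap_train(6000, 125))))
  acts <- rbind(periodic_acts(1, 125, 6000),
                within(periodic_acts(1, 200, 6000), node <- 2L))
  res <- synthetic_result(tr, 2, acts)
  dm <- df_map(res, c(0, 6000))
  expect_equal(dm$df[1], 8, tolerance = dm$resolution_hz)
  expect_equal(dm$df[2], 5, tolerance = dm$resolution_hz)
  expect_true(is.na(dm$df[3]))
  expect_equal(sum(dm$valid) + sum(!dm$valid), 3)
  expect_error(df_map(res, c(0, 9000)), "outside")
})

test_that("COV-DF matches the sample-SD formula", {
  dm <- structure(list(df = c(6, 8, 10), valid = rep(TRUE, 3)),
                  class = "df_map")
  expect_equal(cov_df(dm), 100 * sd(c(6, 8, 10)) / 8)
  expect_equal(cov_df(dm), 25)
  uni <- structure(list(df = rep(7.5, 10), valid = rep(TRUE, 10)),
                   class = "df_map")
  expect_equal(cov_df(uni), 0)
  # scale invariance
  dm2 <- dm
  dm2$df <- dm$df * 3.3
  expect_equal(cov_df(dm2), cov_df(dm))
  expect_error(cov_df(structure(list(df = 5, valid = TRUE),
                                class = "df_map")), "2 valid")
})

test_that("mean AFCL pools per-node intervals", {
  acts <- data.frame(node = c(1, 1, 1, 2, 2, 3),
                     time_ms = c(0, 150, 310, 40, 240, 90))
  res <- synthetic_result(matrix(-80, 3, 500), 2, acts)
  # intervals: node1 {150,160}, node2 {200}; pooled mean 170
  expect_equal(mean_afcl(res), mean(c(150, 160, 200)))
  expect_equal(mean_afcl(res, region_mask = 1), 155)
  quiet <- mean_afcl(res, region_mask = 3)
  expect_true(is.na(quiet))
  # strict pacing recovers the cycle length
  acts2 <- periodic_acts(5, 150, 5000)
  res2 <- synthetic_result(matrix(-80, 5, 2500), 2, acts2)
  expect_equal(mean_afcl(res2), 150, tolerance = 1e-9)
})

test_that("restitution fit recovers the closed-form Smax", {
  A <- 250; B <- 100; tau <- 60
  di <- seq(20, 300, by = 20)
  apd <- A - B * exp(-di / tau)
  ft <- fit_restitution(di, apd)
  want <- (B / tau) * exp(-20 / tau)
  expect_lt(abs(ft$smax - want) / want, 0.01)
  expect_equal(ft$smax, 1.194, tolerance = 0.01)
  flat <- fit_restitution(di, rep(210, length(di)))
  expect_equal(flat$smax, 0)
})

test_that("noisy Smax recovery stays accurate in the median", {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(99)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  errs <- replicate(100, {
    A <- runif(1, 180, 280)
    B <- runif(1, 60, 140)
    tau <- runif(1, 40, 90)
    di <- sort(runif(30, 15, 320))
    apd <- A - B * exp(-di / tau) + rnorm(30, 0, 2)
    truth <- (B / tau) * exp(-min(di) / tau)
    ft <- fit_restitution(di, apd)
    if (is.null(ft)) NA else abs(ft$smax - truth) / truth
  })
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("smax_map extracts in-activity pairs and masks thin nodes", {
  # one node with a restitution-driven AP train: prescribe the DI
  # sequence, derive each APD from the exponential curve, and stack
  # non-overlapping triangular beats; expect a positive Smax and
  # masking below 5 pairs
  di_seq <- rep(c(30, 60, 100, 150, 220, 300), 3)
  dt_s <- 2
  A <- 230; B <- 90; tau <- 70
  onsets <- numeric(0)
  apds <- numeric(0)
  on <- 20
  for (di in di_seq) {
    apd <- A - B * exp(-di / tau)
    onsets <- c(onsets, on)
    apds <- c(apds, apd)
    on <- on + apd + di
  }
  t <- seq(0, on + 300, by = dt_s)
  vm <- rep(-80, length(t))
  for (k in seq_along(onsets)) {
    seg <- t >= onsets[k] & t < onsets[k] + apds[k]
    vm[seg] <- 20 - 100 * ((t[seg] - onsets[k]) / apds[k])
  }
  acts <- data.frame(node = 1L, time_ms = onsets)
  res <- synthetic_result(matrix(vm, 1), dt_s, acts)
  sm <- smax_map(res, c(0, max(t)), min_pairs = 5)
  expect_true(sm$valid[1])
  expect_gt(sm$smax[1], 0)
  short <- synthetic_result(matrix(vm[1:300], 1), dt_s,
                            acts[acts$time_ms < 600, ])
  sm2 <- smax_map(short, c(0, 600), min_pairs = 5)
  expect_false(any(sm2$valid))
})

test_that("outcome classes are exclusive, exhaustive, and correct", {
  n <- 12
  len <- 3001  # samples at 2 ms -> 6000 ms
  # terminated: activity only in the first half
  quiet <- synthetic_result(matrix(-80, n, len), 2,
                            periodic_acts(n, 150, 2500))
  oq <- classify_outcome(quiet, observation_ms = 6000,
                         compute_smax = FALSE)
  expect_equal(oq$classification, "terminated")
  expect_true(oq$defragmented)
  # converted to AT: strictly periodic, spectrally uniform
  tr <- do.call(rbind, lapply(seq_len(n), function(i)
    ap_train(6000, 240, dt_s = 2, phase_ms = i)))
  at <- synthetic_result(tr, 2, periodic_acts(n, 240, 6000))
  oat <- classify_outcome(at, observation_ms = 6000,
                          compute_smax = FALSE)
  expect_equal(oat$classification, "converted_to_at")
  # sustained AF: two spatial domains at different rates
  tr2 <- rbind(
    do.call(rbind, lapply(1:6, function(i) ap_train(6000, 110, dt_s = 2))),
    do.call(rbind, lapply(1:6, function(i) ap_train(6000, 170, dt_s = 2))))
  acts2 <- rbind(periodic_acts(6, 110, 6000),
                 within(periodic_acts(6, 170, 6000), node <- node + 6L))
  af <- synthetic_result(tr2, 2, acts2)
  oaf <- classify_outcome(af, observation_ms = 6000,
                          compute_smax = FALSE)
  expect_equal(oaf$classification, "sustained_af")
  expect_false(oaf$defragmented)
  cls <- c(oq$classification, oat$classification, oaf$classification)
  expect_length(unique(cls), 3)
  # early termination flags the NA contract
  early <- synthetic_result(matrix(-80, n, len), 2,
                            periodic_acts(n, 150, 800))
  oe <- classify_outcome(early, observation_ms = 6000,
                         window_ms = c(3000, 5400), compute_smax = FALSE)
  expect_equal(oe$classification, "terminated")
  expect_true(oe$early_termination)
  expect_true(is.na(oe$mean_afcl_ms))
  expect_true(is.na(oe$mean_df_hz))
})

test_that("phase singularities: a synthetic rotor winds by 2 pi", {
  # rotating wave vm(x, y, t) = f(theta - omega t) around the sheet
  # center carries exactly one singularity at the core
  m <- atrialwave:::strip_mesh(20, 20, 900)
  ctr <- c(10.37, 10.22)  # generic position, off the lattice nodes
  th <- atan2(m$nodes[, 2] - ctr[2], m$nodes[, 1] - ctr[1])
  period <- 150
  times <- seq(0, 600, by = 2)
  vm <- outer(th, times, function(a, tt)
    -80 + 100 * (0.5 + 0.5 * cos(a - 2 * pi * tt / period)))
  res <- synthetic_result(vm, 2)
  ps_all <- phase_singularities(res, m, c(200, 300, 400),
                                tau_ms = period / 4)
  expect_true(all(ps_all$n_singularities >= 1))
  ps_core <- phase_singularities(res, m, 300, center = ctr,
                                 radius_mm = 3, tau_ms = period / 4)
  expect_gte(ps_core$n_singularities, 1)
  ps_far <- phase_singularities(res, m, 300, center = c(2, 18),
                                radius_mm = 2, tau_ms = period / 4)
  expect_equal(ps_far$n_singularities, 0)
})

test_that("a planar wave carries no phase singularities", {
  m <- atrialwave:::strip_mesh(16, 10, 800)
  pace <- which(m$nodes[, 1] < 1.5)
  res <- run_tissue(m, preset_scales("af_remodeling"),
                    list(stim_event(pace, 1, 3, -40),
                         stim_event(pace, 201, 3, -40)),
                    duration_ms = 320, d_longitudinal = 0.12,
                    d_transverse = 0.12, dt_ms = 0.05,
                    record_interval_ms = 2)
  ps <- phase_singularities(res, m, seq(40, 280, by = 40), tau_ms = 8)
  expect_true(all(ps$n_singularities == 0))
})

test_that("highest-DF site honors exclusions and ties", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = TRUE)
  dfv <- rep(5, nrow(m$nodes))
  corridor <- gap_corridor_nodes(m, les, "left_ant")
  dfv[corridor[1]] <- 12  # global max inside an exclusion zone
  far <- which(m$nodes[, 1] > 15 & m$region == "la_body")
  dfv[far[1]] <- 9
  dm <- structure(list(df = dfv, valid = rep(TRUE, length(dfv))),
                  class = "df_map")
  expect_equal(highest_df_site(dm, m, les, exclusion_radius_mm = 3),
               far[1])
  # tie -> lowest node id
  dfv2 <- rep(5, nrow(m$nodes))
  dfv2[c(far[2], far[1])] <- 9
  dm2 <- structure(list(df = dfv2, valid = rep(TRUE, length(dfv2))),
                   class = "df_map")
  expect_equal(highest_df_site(dm2, m, NULL), min(far[1], far[2]))
  none <- structure(list(df = dfv, valid = rep(FALSE, length(dfv))),
                    class = "df_map")
  expect_error(highest_df_site(none, m, les), "no valid node")
})

test_that("gap wave-break detection sees transits through a corridor", {
  # real (small) run: gapped PVI, pace the body, waves cross into the
  # PV compartment through the gaps; transits must be detected with
  # la_to_pv direction
  m <- build_idealized_la(26, 26, target_edge_um = 800, pv_radius_mm = 2.6,
                          seed = 2)
  les <- make_pvi_lesions(m, with_gaps = TRUE, gap_width_mm = 2)
  mg <- apply_lesions(m, les)
  pace <- pacing_site <- which(mg$nodes[, 1] < 1.5 &
                               mg$tissue != "ablated")
  res <- run_tissue(mg, preset_scales("af_remodeling"),
                    list(stim_event(pace, 1, 3, -40)),
                    duration_ms = 220, d_longitudinal = 0.12,
                    d_transverse = 0.12, dt_ms = 0.05,
                    record_interval_ms = 2)
  wb <- detect_gap_wavebreaks(res, mg, les)
  expect_setequal(wb$gap_id, gap_ids(les))
  expect_true(any(wb$transits >= 1))
  # gaps facing the incoming wave (the "post" side of each ring) must
  # carry outside-in transits; the far-side gaps can legitimately be
  # crossed from the PV interior first
  facing <- wb[wb$gap_id %in% c("left_post", "right_post"), ]
  expect_true(all(facing$la_to_pv >= 1))
  expect_true(all(facing$pv_to_la == 0))
  # quiescent recording: zero transits, zero breaks
  quiet <- run_tissue(mg, preset_scales("af_remodeling"), NULL,
                      duration_ms = 60, d_longitudinal = 0.12,
                      d_transverse = 0.12, dt_ms = 0.05,
                      record_interval_ms = 2)
  wq <- detect_gap_wavebreaks(quiet, mg, les)
  expect_true(all(wq$transits == 0))
  expect_true(all(wq$break_count == 0))
  nogap <- make_pvi_lesions(m, with_gaps = FALSE)
  expect_error(detect_gap_wavebreaks(res, mg, nogap), "no unfilled gaps")
})
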