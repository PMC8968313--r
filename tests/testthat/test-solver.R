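# Monodomain solver: operator structure, planar propagation, CV
# measurement/calibration, the induction protocol, and determinism.

test_that("diffusion operator conserves a uniform field", {
  m <- small_la_mesh()
  op <- build_diffusion_operator(m, 0.1, 0.02)
  u <- rep(3.7, length(op$active))
  expect_lt(max(abs(as.numeric(op$L %*% u))), 1e-9)
  expect_error(build_diffusion_operator(m, 0.01, 0.05), "d_longitudinal")
})

test_that("isotropic operator reproduces the Laplacian of a quadratic", {
  # on a uniform strip, L applied to x^2 + y^2 must give 4 d at interior
  # nodes (the FEM discretization is exact for quadratics up to
  # boundary effects)
  m <- atrialwave:::strip_mesh(20, 10, 800)
  d <- 0.07
  op <- build_diffusion_operator(m, d, d)
  xy <- m$nodes[op$active, , drop = FALSE]
  q <- xy[, 1]^2 + xy[, 2]^2
  lap <- as.numeric(op$L %*% q)
  interior <- which(xy[, 1] > 3 & xy[, 1] < 17 & xy[, 2] > 3 &
                    xy[, 2] < 7)
  expect_lt(max(abs(lap[interior] - 4 * d)), 0.05 * 4 * d)
})

test_that("ablated nodes are absent from the operator", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = FALSE)
  mc <- apply_lesions(m, les)
  op <- build_diffusion_operator(mc, 0.1, 0.02)
  expect_equal(length(op$active), sum(mc$tissue != "ablated"))
  expect_equal(dim(op$L), rep(sum(mc$tissue != "ablated"), 2))
  all_abl <- mc
  all_abl$tissue[] <- "ablated"
  expect_error(build_diffusion_operator(all_abl, 0.1, 0.02),
               "no non-ablated")
})

test_that("induction protocol arithmetic matches its definition", {
  p <- af_induction_protocol(1)
  expect_equal(protocol_span_ms(p), 11520)
  expect_length(p, 72)  # 9 levels x 8 beats
  onsets <- vapply(p, `[[`, numeric(1), "onset_ms")
  expect_equal(onsets[1], 0)
  expect_equal(diff(onsets)[1:8], rep(200, 8))
  expect_equal(tail(diff(onsets), 7), rep(120, 7))
  one <- af_induction_protocol(1, 200, 200, 10, 8)
  expect_length(one, 8)
  expect_equal(protocol_span_ms(one), 1600)
  expect_error(af_induction_protocol(1, 200, 125, 10), "divisible")
  expect_error(af_induction_protocol(1, 100, 200), "start_cl_ms")
})

test_that("a quiescent sheet stays quiescent", {
  m <- atrialwave:::strip_mesh(10, 6, 900)
  res <- run_tissue(m, preset_scales("baseline"), NULL,
                    duration_ms = 100, d_longitudinal = 0.1,
                    d_transverse = 0.1, dt_ms = 0.05)
  expect_equal(nrow(res$activations), 0)
  expect_lt(diff(range(res$vm)), 0.5)
})

test_that("a planar wave activates every node once, ordered by distance", {
  m <- atrialwave:::strip_mesh(16, 6, 800)
  pace <- which(m$nodes[, 1] < 1.5)
  res <- run_tissue(m, preset_scales("af_remodeling"),
                    list(stim_event(pace, 1, 3, -40)),
                    duration_ms = 90, d_longitudinal = 0.15,
                    d_transverse = 0.15, dt_ms = 0.05)
  acts <- res$activations
  expect_equal(sort(unique(acts$node)), seq_len(nrow(m$nodes)))
  expect_equal(nrow(acts), nrow(m$nodes))  # exactly once
  # activation time increases with x
  ord <- acts$time_ms[match(seq_len(nrow(m$nodes)), acts$node)]
  fit <- cor(ord, m$nodes[, 1])
  expect_gt(fit, 0.99)
  # CV measurement is distance / time
  pa <- which.min(abs(m$nodes[, 1] - 4) + abs(m$nodes[, 2] - 3))
  pb <- which.min(abs(m$nodes[, 1] - 12) + abs(m$nodes[, 2] - 3))
  cv <- measure_cv(res, m, pa, pb)
  dist <- sqrt(sum((m$nodes[pa, ] - m$nodes[pb, ])^2))
  dtv <- abs(ord[pb] - ord[pa])
  expect_equal(cv, dist / dtv)
  expect_error(measure_cv(res, m, pa, pa), "distinct")
})

test_that("conduction is faster along fibers than across", {
  along <- atrialwave:::planar_cv(0.15, 0.03, edge_um = 800)
  m <- atrialwave:::strip_mesh(16, 8, 800)
  m$fibers <- cbind(rep(0, nrow(m$nodes)), rep(1, nrow(m$nodes)))
  across <- atrialwave:::planar_cv(0.15, 0.03, edge_um = 800, strip = m)
  expect_gt(along, 1.5 * across)
})

test_that("halving dt changes planar CV by under 2 percent", {
  cv1 <- atrialwave:::planar_cv(0.12, 0.12, edge_um = 800, dt_ms = 0.05)
  cv2 <- atrialwave:::planar_cv(0.12, 0.12, edge_um = 800, dt_ms = 0.025)
  expect_lt(abs(cv1 - cv2) / cv2, 0.02)
})

test_that("tabulated and exact kernels agree at tissue scale", {
  m <- atrialwave:::strip_mesh(8, 5, 900)
  pace <- which(m$nodes[, 1] < 1.5)
  args <- list(m, preset_scales("af_remodeling"),
               list(stim_event(pace, 1, 3, -40)), duration_ms = 40,
               d_longitudinal = 0.12, d_transverse = 0.12, dt_ms = 0.05)
  tab <- do.call(run_tissue, c(args, use_tables = TRUE))
  exact <- do.call(run_tissue, c(args, use_tables = FALSE))
  expect_lt(max(abs(tab$vm - exact$vm)), 0.1)  # mV
})

test_that("tissue runs are bit-reproducible", {
  m <- generate_fibrosis(atrialwave:::strip_mesh(10, 6, 900), 0.2,
                         seed = 4)
  pace <- which(m$nodes[, 1] < 1.5)
  args <- list(m, preset_scales("af_remodeling"),
               list(stim_event(pace, 1, 3, -40)), duration_ms = 60,
               d_longitudinal = 0.12, dt_ms = 0.05)
  a <- do.call(run_tissue, args)
  b <- do.call(run_tissue, args)
  expect_identical(a$vm, b$vm)
  expect_identical(a$activations, b$activations)
  expect_identical(a$final_states, b$final_states)
})

test_that("calibration converges and the CV-d relation is monotone", {
  cal <- calibrate_diffusion(0.45, tolerance = 0.05, edge_um = 700,
                             dt_ms = 0.05)
  expect_lt(abs(cal$achieved_cv - 0.45) / 0.45, 0.05)
  h <- cal$history[!is.na(cal$history$cv), ]
  h <- h[order(h$d), ]
  expect_true(all(diff(h$cv) > -1e-9))
  expect_error(calibrate_diffusion(0), "target_cv")
})

test_that("an ablation line blocks unless it carries a 2-mm gap", {
  m <- atrialwave:::strip_mesh(20, 8, 700)
  # vertical ablated line at x ~ 10, optionally with a 2-mm gap at mid
  line <- abs(m$nodes[, 1] - 10) < 0.8
  blocked <- m
  blocked$tissue[line] <- "ablated"
  gapped <- m
  gapped$tissue[line & abs(m$nodes[, 2] - 4) > 1] <- "ablated"
  pace <- which(m$nodes[, 1] < 1.5)
  distal <- which(m$nodes[, 1] > 12)
  for (case in list(list(mesh = blocked, expect_distal = FALSE),
                    list(mesh = gapped, expect_distal = TRUE))) {
    res <- run_tissue(case$mesh, preset_scales("af_remodeling"),
                      list(stim_event(pace, 1, 3, -40)),
                      duration_ms = 120, d_longitudinal = 0.15,
                      d_transverse = 0.15, dt_ms = 0.05)
    got <- any(res$activations$node %in% distal)
    expect_identical(got, case$expect_distal)
    # ablated nodes never activate
    expect_false(any(res$activations$node %in%
                     which(case$mesh$tissue == "ablated")))
  }
})
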