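# Shared fixtures: small meshes and synthetic simulation results built in
# code at test time.

small_la_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_idealized_la(30, 30, target_edge_um = 700,
                                   pv_radius_mm = 3, seed = 1)
    cache
  }
})

# independent connected-components oracle: plain BFS over the non-ablated
# adjacency, no igraph
bfs_components <- function(mesh) {
  n <- nrow(mesh$nodes)
  keep <- mesh$tissue != "ablated"
  e <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
             mesh$triangles[, c(1, 3)])
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1]]] <- c(adj[[e[r, 1]]], e[r, 2])
    adj[[e[r, 2]]] <- c(adj[[e[r, 2]]], e[r, 1])
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in which(keep)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (wn in adj[[u]]) {
        if (is.na(comp[wn])) {
          comp[wn] <- cur
          queue <- c(queue, wn)
        }
      }
    }
  }
  comp
}

bfs_connected <- function(mesh, a, b) {
  comp <- bfs_components(mesh)
  length(intersect(unique(na.omit(comp[a])),
                   unique(na.omit(comp[b])))) > 0
}

# synthetic simulation_result with prescribed per-node voltage traces and
# activation times; traces is nodes x samples
synthetic_result <- function(traces, record_interval_ms = 2,
                             activations = NULL, t0_ms = 0,
                             region = NULL, tissue = NULL) {
  n <- nrow(traces)
  ns <- ncol(traces)
  times <- t0_ms + (seq_len(ns) - 1) * record_interval_ms
  if (is.null(activations))
    activations <- data.frame(node = integer(), time_ms = numeric())
  if (is.null(region)) region <- rep("la_body", n)
  if (is.null(tissue)) tissue <- rep("normal", n)
  structure(list(
    vm = traces, times = times, record_nodes = seq_len(n),
    activations = activations,
    duration_ms = times[ns] - t0_ms, dt_ms = record_interval_ms,
    record_interval_ms = record_interval_ms, t0_ms = t0_ms,
    active = seq_len(n), final_states = NULL, last_act = rep(-1e9, n),
    tissue = tissue, region = region, meta = list()),
    class = "simulation_result")
}

# periodic action-potential-like train: exponential upstroke/plateau pulse
# of width `apd` repeating with period `cl`, sampled every dt_s ms
ap_train <- function(duration_ms, cl_ms, apd_ms = 0.6 * cl_ms,
                     dt_s = 2, phase_ms = 0) {
  t <- seq(0, duration_ms, by = dt_s)
  ph <- (t - phase_ms) %% cl_ms
  vm <- ifelse(ph < apd_ms,
               20 - 100 * (ph / apd_ms)^2, -80)
  vm
}

# activation table for a strictly periodic activation of every node
periodic_acts <- function(n_nodes, cl_ms, t_end_ms, t_start_ms = 0,
                          jitter = 0) {
  do.call(rbind, lapply(seq_len(n_nodes), function(nd) {
    tt <- seq(t_start_ms + (nd %% 7), t_end_ms, by = cl_ms)
    data.frame(node = nd, time_ms = tt)
  }))
}
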