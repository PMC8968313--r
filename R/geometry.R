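# Idealized left-atrium-like synthetic geometry: a flat triangulated sheet
# with four disc-shaped pulmonary-vein (PV) sleeve regions, fiber vectors,
# and a clustered fibrosis label field. Stands in for patient CT /
# electroanatomical anatomy while preserving the topological essentials:
# two encirclable PV pairs and an extra-PV atrial body.

# regular (near-equilateral) triangular lattice covering [0,w] x [0,h]
tri_lattice <- function(width_mm, height_mm, edge_mm) {
  h <- edge_mm
  rh <- h * sqrt(3) / 2
  nx <- max(3L, round(width_mm / h) + 1L)
  ny <- max(3L, round(height_mm / rh) + 1L)
  xs <- seq(0, width_mm, length.out = nx)
  ys <- seq(0, height_mm, length.out = ny)
  dx <- xs[2] - xs[1]
  nodes <- matrix(0, nx * ny, 2)
  for (r in seq_len(ny)) {
    off <- if (r %% 2 == 0) dx / 2 else 0
    idx <- (r - 1L) * nx + seq_len(nx)
    nodes[idx, 1] <- xs + off
    nodes[idx, 2] <- ys[r]
  }
  tri <- vector("list", ny - 1L)
  for (r in seq_len(ny - 1L)) {
    a <- (r - 1L) * nx + seq_len(nx - 1L)  # row r, cols c..c+1
    b <- r * nx + seq_len(nx - 1L)         # row r+1
    if (r %% 2 == 1L) {
      # row r not offset, row r+1 offset right
      t1 <- cbind(a, a + 1L, b)
      t2 <- cbind(a + 1L, b + 1L, b)
    } else {
      t1 <- cbind(a, a + 1L, b + 1L)
      t2 <- cbind(a, b + 1L, b)
    }
    tri[[r]] <- rbind(t1, t2)
  }
  bnd <- rep(FALSE, nx * ny)
  bnd[seq_len(nx)] <- TRUE
  bnd[(ny - 1L) * nx + seq_len(nx)] <- TRUE
  bnd[seq(1L, nx * ny, by = nx)] <- TRUE
  bnd[seq(nx, nx * ny, by = nx)] <- TRUE
  tri <- do.call(rbind, tri)
  storage.mode(tri) <- "integer"
  dimnames(tri) <- NULL
  list(nodes = nodes, triangles = tri, boundary = bnd)
}

#' Generate an idealized LA-like sheet with four PV sleeve regions
#'
#' Builds a flat rectangular triangulated sheet (near-equilateral lattice
#' with seeded interior jitter) carrying four disc-shaped PV sleeve
#' regions: a "left" pair and a "right" pair, each pair vertically
#' adjacent so a single circumferential lesion can encircle it. Boundary
#' nodes are tagged; default fibers run along x with a circumferential
#' deflection around each PV ostium.
#'
#' @param width_mm,height_mm Sheet dimensions (mm).
#' @param target_edge_um Target mean edge length (um), >= 100. The
#'   clinical-resolution value is 235 um; desk-scale work uses coarser
#'   meshes (400-700 um).
#' @param pv_radius_mm PV sleeve disc radius (mm).
#' @param seed Seed for the interior node jitter.
#' @param jitter Interior jitter amplitude as a fraction of the edge
#'   length (default 0.1).
#' @return An `atrial_mesh`: list with `nodes` (n x 2, mm), `triangles`
#'   (m x 3, 1-based), per-node `region`
#'   (`la_body`/`pv1`..`pv4`/`boundary`), `tissue`
#'   (`normal`/`fibrotic`/`ablated`), unit `fibers` (n x 2), and summary
#'   metadata including the achieved mean/SD edge length in um.
#' @export
#' @examples
#' m <- build_idealized_la(30, 30, target_edge_um = 1500)
#' table(m$region)
build_idealized_la <- function(width_mm = 50, height_mm = 50,
                               target_edge_um = 400, pv_radius_mm = 3,
                               seed = 1L, jitter = 0.1) {
  if (target_edge_um < 100) stop("target_edge_um must be >= 100")
  h <- target_edge_um / 1000
  r <- pv_radius_mm
  cx <- c(0.25, 0.25, 0.75, 0.75) * width_mm
  cy <- c(0.30, 0.70, 0.30, 0.70) * height_mm
  pv_centers <- cbind(x = cx, y = cy)
  rownames(pv_centers) <- paste0("pv", 1:4)
  # geometric feasibility: discs must be disjoint and clear of the boundary
  sep <- sqrt((cx[1] - cx[2])^2 + (cy[1] - cy[2])^2)
  if (sep <= 2 * r)
    stop("geometric infeasibility: PV ostia overlap ",
         "(pair separation ", round(sep, 2), " mm <= 2 x pv_radius)")
  if (any(cx - r <= 0) || any(cx + r >= width_mm) ||
      any(cy - r <= 0) || any(cy + r >= height_mm))
    stop("geometric infeasibility: PV ostium touches the sheet boundary")

  lat <- tri_lattice(width_mm, height_mm, h)
  nodes <- lat$nodes
  n <- nrow(nodes)
  if (jitter > 0) {
    jit <- with_local_seed(seed, matrix(runif(2L * n, -jitter * h,
                                              jitter * h), n, 2))
    jit[lat$boundary, ] <- 0
    nodes <- nodes + jit
  }

  region <- rep("la_body", n)
  for (k in 1:4) {
    d <- sqrt((nodes[, 1] - cx[k])^2 + (nodes[, 2] - cy[k])^2)
    region[d <= r] <- paste0("pv", k)
  }
  region[lat$boundary] <- "boundary"
  if (any(table(factor(region, levels = paste0("pv", 1:4))) == 0))
    stop("geometric infeasibility: a PV region captured no nodes ",
         "(mesh too coarse for pv_radius_mm)")

  # fibers: uniform x-direction, deflected circumferentially near ostia
  fib <- cbind(rep(1, n), rep(0, n))
  for (k in 1:4) {
    dx <- nodes[, 1] - cx[k]
    dy <- nodes[, 2] - cy[k]
    d <- sqrt(dx^2 + dy^2)
    near <- d < 2.5 * r & d > 1e-9
    a <- pmax(0, 1 - d[near] / (2.5 * r))
    tx <- -dy[near] / d[near]
    ty <- dx[near] / d[near]
    fib[near, 1] <- (1 - a) * fib[near, 1] + a * tx
    fib[near, 2] <- (1 - a) * fib[near, 2] + a * ty
  }
  nrm <- sqrt(rowSums(fib^2))
  nrm[nrm < 1e-12] <- 1
  fib <- fib / nrm

  mesh <- structure(list(
    nodes = nodes, triangles = lat$triangles,
    region = region, tissue = rep("normal", n), fibers = fib,
    pv_centers = pv_centers, pv_radius_mm = pv_radius_mm,
    pv_pairs = list(left = c("pv1", "pv2"), right = c("pv3", "pv4")),
    width_mm = width_mm, height_mm = height_mm,
    target_edge_um = target_edge_um, seed = seed),
    class = "atrial_mesh")
  es <- edge_length_stats(mesh)
  mesh$edge_mean_um <- es$mean_um
  mesh$edge_sd_um <- es$sd_um
  mesh
}

#' Unique edges of a mesh
#' @param mesh An `atrial_mesh`.
#' @return Two-column integer matrix of node-id pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mean and SD of mesh edge lengths
#' @param mesh An `atrial_mesh`.
#' @return List with `mean_um` and `sd_um`.
#' @export
edge_length_stats <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                     mesh$nodes[e[, 2], , drop = FALSE])^2))
  list(mean_um = mean(d) * 1000, sd_um = sd(d) * 1000)
}

#' Clustered fibrotic label field
#'
#' Labels a target fraction of the non-ablated LA-body nodes as fibrotic
#' using seeded cluster growth: random seed nodes are drawn and grown into
#' discs of randomized radius around `cluster_radius_mm` until the target
#' count is met (the last cluster is trimmed from its rim inward), which
#' mimics the patchy fibrosis seen in voltage maps. Identical seeds give
#' identical label vectors.
#'
#' @param mesh An `atrial_mesh`.
#' @param density_fraction Target fibrotic fraction of eligible nodes, in
#'   `[0, 1)`.
#' @param cluster_radius_mm Nominal cluster radius (mm).
#' @param seed RNG seed.
#' @return The mesh with updated `tissue` labels.
#' @export
generate_fibrosis <- function(mesh, density_fraction,
                              cluster_radius_mm = 2.5, seed = 1L) {
  if (density_fraction < 0 || density_fraction >= 1)
    stop("density_fraction must be in [0, 1)")
  eligible <- which(mesh$region == "la_body" & mesh$tissue != "ablated")
  mesh$tissue[mesh$tissue == "fibrotic"] <- "normal"
  target <- round(density_fraction * length(eligible))
  if (target == 0) return(mesh)
  chosen <- with_local_seed(seed, {
    sel <- logical(length(eligible))
    xy <- mesh$nodes[eligible, , drop = FALSE]
    guard <- 0L
    while (sum(sel) < target && guard < 10000L) {
      guard <- guard + 1L
      open <- which(!sel)
      ctr <- open[sample.int(length(open), 1L)]
      rad <- cluster_radius_mm * runif(1, 0.5, 1.5)
      d <- sqrt((xy[, 1] - xy[ctr, 1])^2 + (xy[, 2] - xy[ctr, 2])^2)
      cl <- which(!sel & d <= rad)
      need <- target - sum(sel)
      if (length(cl) > need) cl <- cl[order(d[cl])][seq_len(need)]
      sel[cl] <- TRUE
    }
    eligible[sel]
  })
  mesh$tissue[chosen] <- "fibrotic"
  mesh
}

#' Inverse-distance-weighted interpolation onto mesh nodes
#'
#' Interpolates sparse sample values (e.g. electroanatomical map points)
#' onto every mesh node with weights `d^(-power)`. A node coincident with
#' a sample point (distance < `eps`) takes that sample's value exactly.
#'
#' @param sample_xy k x 2 matrix of sample coordinates (mm).
#' @param values Length-k sample values.
#' @param mesh An `atrial_mesh`.
#' @param power IDW exponent, default 2.
#' @param eps Coincidence tolerance (mm).
#' @return Numeric vector of per-node values.
#' @export
idw_interpolate <- function(sample_xy, values, mesh, power = 2,
                            eps = 1e-9) {
  sample_xy <- matrix(as.numeric(sample_xy), ncol = 2)
  if (nrow(sample_xy) < 1L) stop("at least one sample point is required")
  if (length(values) != nrow(sample_xy))
    stop("values must match the number of sample points")
  dx <- outer(mesh$nodes[, 1], sample_xy[, 1], "-")
  dy <- outer(mesh$nodes[, 2], sample_xy[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  w <- d^(-power)
  out <- as.numeric((w %*% values) / rowSums(w))
  hit <- which(d < eps, arr.ind = TRUE)
  if (nrow(hit)) out[hit[, 1]] <- values[hit[, 2]]
  out
}

# igraph of the non-ablated tissue adjacency
tissue_graph <- function(mesh) {
  keep <- mesh$tissue != "ablated"
  e <- mesh_edges(mesh)
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(mesh$nodes), directed = FALSE)
  igraph::add_edges(g, t(e))
}

#' Connected components of the non-ablated tissue
#'
#' @param mesh An `atrial_mesh`.
#' @return Integer component id per node; `NA` for ablated nodes.
#' @export
mesh_components <- function(mesh) {
  g <- tissue_graph(mesh)
  comp <- igraph::components(g)$membership
  comp[mesh$tissue == "ablated"] <- NA_integer_
  comp
}

#' Are two node regions electrically connected?
#'
#' @param mesh An `atrial_mesh`.
#' @param nodes_a,nodes_b Node-id vectors.
#' @return TRUE if any non-ablated node of `nodes_a` shares a connected
#'   component of the non-ablated adjacency graph with any of `nodes_b`.
#' @export
regions_connected <- function(mesh, nodes_a, nodes_b) {
  comp <- mesh_components(mesh)
  a <- stats::na.omit(comp[nodes_a])
  b <- stats::na.omit(comp[nodes_b])
  length(intersect(a, b)) > 0
}

#' @export
print.atrial_mesh <- function(x, ...) {
  cat("atrial_mesh:", nrow(x$nodes), "nodes,", nrow(x$triangles),
      "triangles\n")
  cat("  sheet", x$width_mm, "x", x$height_mm,
      "mm; mean edge", round(x$edge_mean_um, 1), "um (SD",
      paste0(round(x$edge_sd_um, 1), ")"), "\n")
  cat("  regions:", paste(names(table(x$region)), table(x$region),
                          collapse = ", "), "\n")
  cat("  tissue:", paste(names(table(x$tissue)), table(x$tissue),
                         collapse = ", "), "\n")
  invisible(x)
}
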