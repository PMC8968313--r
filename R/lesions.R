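# Virtual ablation lesion sets: circumferential PV isolation rings with
# optional conduction gaps, gap fills, and focal discs. Ablation is
# modeled as a permanent conduction block: ablated nodes are removed from
# the diffusion domain and never activate.

# closed capsule path at distance `radius` around the vertical segment
# joining two PV centers; returns points (k x 2), cumulative arc length,
# and total length. Orientation: up the right side, over the top, down
# the left, around the bottom. s = 0 at the right-side midpoint.
ring_path <- function(c_lo, c_hi, radius, ds = 0.2) {
  cx <- c_lo[1]
  y1 <- c_lo[2]
  y2 <- c_hi[2]
  stopifnot(y2 > y1)
  seg <- function(p, q) {
    L <- sqrt(sum((q - p)^2))
    k <- max(2L, ceiling(L / ds) + 1L)
    t <- seq(0, 1, length.out = k)[-1]
    cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  arc <- function(ctr, a0, a1) {
    L <- abs(a1 - a0) * radius
    k <- max(2L, ceiling(L / ds) + 1L)
    a <- seq(a0, a1, length.out = k)[-1]
    cbind(ctr[1] + radius * cos(a), ctr[2] + radius * sin(a))
  }
  mid_r <- c(cx + radius, (y1 + y2) / 2)
  pts <- rbind(
    mid_r,
    seg(mid_r, c(cx + radius, y2)),
    arc(c(cx, y2), 0, pi),
    seg(c(cx - radius, y2), c(cx - radius, y1)),
    arc(c(cx, y1), pi, 2 * pi),
    seg(c(cx + radius, y1), mid_r))
  dseg <- sqrt(rowSums((pts - rbind(pts[nrow(pts), ], pts[-nrow(pts), ]))^2))
  dseg[1] <- 0
  list(pts = pts, s = cumsum(dseg),
       total = sum(dseg) + sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)))
}

# for each query point: distance to the nearest path point and its arc
# position s
path_project <- function(xy, path) {
  n <- nrow(xy)
  d2 <- outer(xy[, 1], path$pts[, 1], "-")^2 +
        outer(xy[, 2], path$pts[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  list(dist = sqrt(d2[cbind(seq_len(n), j)]), s = path$s[j])
}

arc_dist <- function(s, s0, total) {
  d <- abs(s - s0) %% total
  pmin(d, total - d)
}

#' Build PV isolation lesion sets (complete or with conduction gaps)
#'
#' Creates two circumferential ablation rings, one encircling each PV
#' pair. With `with_gaps = TRUE`, unablated corridors of arc width
#' `gap_width_mm` are left on the anterior and posterior side of each
#' ring (opposite arc positions), four gaps in total by default, each
#' with a stable identifier.
#'
#' @param mesh An `atrial_mesh`.
#' @param with_gaps Leave conduction gaps in the rings?
#' @param gap_width_mm Arc width of each gap (mm), default 2.
#' @param gaps_per_model Total number of gaps (even; split across the two
#'   rings), default 4.
#' @param ring_margin_mm Clearance between the PV sleeve edge and the
#'   ring centerline (mm).
#' @param line_width_mm Ablation line width (mm); default
#'   `max(1, 2.5 x mean edge)` so lines are contiguous at mesh
#'   resolution.
#' @return A `lesion_set`.
#' @export
make_pvi_lesions <- function(mesh, with_gaps = FALSE, gap_width_mm = 2,
                             gaps_per_model = 4, ring_margin_mm = 1.5,
                             line_width_mm = NULL) {
  if (gap_width_mm <= 0) stop("gap_width_mm must be > 0")
  if (with_gaps && gaps_per_model %% 2 != 0)
    stop("gaps_per_model must be even (gaps are split across two rings)")
  edge_mm <- mesh$edge_mean_um / 1000
  if (is.null(line_width_mm)) line_width_mm <- max(1, 2.5 * edge_mm)
  if (line_width_mm < edge_mm)
    stop("line_width_mm must be >= the mean edge length")
  radius <- mesh$pv_radius_mm + ring_margin_mm
  if (line_width_mm / 2 >= ring_margin_mm)
    stop("line width overlaps the PV sleeve; increase ring_margin_mm")

  lesions <- list()
  for (side in names(mesh$pv_pairs)) {
    pair <- mesh$pv_pairs[[side]]
    ctrs <- mesh$pv_centers[pair, , drop = FALSE]
    ord <- order(ctrs[, 2])
    c_lo <- ctrs[ord[1], ]
    c_hi <- ctrs[ord[2], ]
    if (c_lo[1] - radius - line_width_mm / 2 <= 0 ||
        c_lo[1] + radius + line_width_mm / 2 >= mesh$width_mm ||
        c_lo[2] - radius - line_width_mm / 2 <= 0 ||
        c_hi[2] + radius + line_width_mm / 2 >= mesh$height_mm)
      stop("ring cannot be routed: ostium too close to the sheet boundary")
    path <- ring_path(c_lo, c_hi, radius)
    gaps <- list()
    if (with_gaps) {
      per_ring <- gaps_per_model / 2
      # anterior (s = 0, right-side midpoint) and posterior (s = L/2)
      pos <- (seq_len(per_ring) - 1L) * path$total / per_ring
      lab <- c("ant", "post", paste0("x", seq_len(max(0, per_ring - 2))))
      for (g in seq_len(per_ring)) {
        gaps[[g]] <- list(id = paste(side, lab[g], sep = "_"),
                          s_center = pos[g], width_mm = gap_width_mm,
                          filled = FALSE)
      }
    }
    lesions[[length(lesions) + 1L]] <- list(
      type = "ring", name = side, pair = pair,
      radius = radius, width_mm = line_width_mm, path = path, gaps = gaps)
  }
  structure(list(lesions = lesions), class = "lesion_set")
}

#' Identifiers of the (unfilled) gaps in a lesion set
#' @param lesions A `lesion_set`.
#' @param include_filled Also list filled gaps?
#' @return Character vector of gap ids.
#' @export
gap_ids <- function(lesions, include_filled = FALSE) {
  unlist(lapply(lesions$lesions, function(l) {
    if (l$type != "ring") return(character())
    vapply(l$gaps, function(g) {
      if (g$filled && !include_filled) NA_character_ else g$id
    }, character(1))
  })) -> ids
  ids[!is.na(ids)]
}

#' Convert named gaps into ablation segments
#'
#' Filling all gaps of a gapped PVI yields a lesion set whose applied
#' ablated-node set equals the complete-PVI set.
#'
#' @param lesions A `lesion_set`.
#' @param ids Gap identifiers to fill (see [gap_ids()]).
#' @return The modified `lesion_set`.
#' @export
fill_gaps <- function(lesions, ids) {
  if (!length(ids)) return(lesions)
  known <- gap_ids(lesions, include_filled = TRUE)
  unknown <- setdiff(ids, known)
  if (length(unknown))
    stop("unknown gap id(s): ", paste(unknown, collapse = ", "))
  lesions$lesions <- lapply(lesions$lesions, function(l) {
    if (l$type == "ring")
      l$gaps <- lapply(l$gaps, function(g) {
        if (g$id %in% ids) g$filled <- TRUE
        g
      })
    l
  })
  lesions
}

#' Focal disc lesion
#'
#' @param mesh An `atrial_mesh`.
#' @param center_node Node id at the lesion center.
#' @param radius_mm Disc radius (mm), >= the mean edge length.
#' @return A `lesion_set` containing one focal lesion.
#' @export
make_focal_lesion <- function(mesh, center_node, radius_mm) {
  if (radius_mm < mesh$edge_mean_um / 1000)
    stop("radius_mm must be >= the mean edge length")
  structure(list(lesions = list(list(
    type = "focal", name = paste0("focal_", center_node),
    center_node = center_node,
    center = mesh$nodes[center_node, ], radius_mm = radius_mm,
    gaps = list()))), class = "lesion_set")
}

#' Combine lesion sets
#' @param ... `lesion_set` objects.
#' @return A single `lesion_set` with all lesions.
#' @export
combine_lesions <- function(...) {
  sets <- list(...)
  structure(list(lesions = do.call(c, lapply(sets, `[[`, "lesions"))),
            class = "lesion_set")
}

# node ids ablated by a lesion set (gap corridors excluded)
lesion_nodes <- function(mesh, lesions) {
  abl <- logical(nrow(mesh$nodes))
  for (l in lesions$lesions) {
    if (l$type == "ring") {
      pr <- path_project(mesh$nodes, l$path)
      band <- pr$dist <= l$width_mm / 2
      for (g in l$gaps) {
        if (!g$filled)
          band <- band & !(arc_dist(pr$s, g$s_center, l$path$total) <=
                           g$width_mm / 2)
      }
      abl <- abl | band
    } else if (l$type == "focal") {
      d <- sqrt((mesh$nodes[, 1] - l$center[1])^2 +
                (mesh$nodes[, 2] - l$center[2])^2)
      abl <- abl | d <= l$radius_mm
    }
  }
  which(abl)
}

#' Apply lesions to a mesh
#'
#' Labels every node inside the lesion geometry as `ablated` (idempotent;
#' other labels untouched). Ablated nodes are removed from the diffusion
#' domain by the solver, producing a permanent conduction block.
#'
#' @param mesh An `atrial_mesh`.
#' @param lesions A `lesion_set`.
#' @return The mesh with updated tissue labels.
#' @export
apply_lesions <- function(mesh, lesions) {
  mesh$tissue[lesion_nodes(mesh, lesions)] <- "ablated"
  mesh
}

#' Nodes in a gap's conduction corridor
#'
#' @param mesh An `atrial_mesh`.
#' @param lesions A `lesion_set`.
#' @param id A gap identifier.
#' @return Node ids lying in the ring band at the gap's arc interval.
#' @export
gap_corridor_nodes <- function(mesh, lesions, id) {
  for (l in lesions$lesions) {
    if (l$type != "ring") next
    for (g in l$gaps) {
      if (g$id == id) {
        pr <- path_project(mesh$nodes, l$path)
        return(which(pr$dist <= l$width_mm / 2 &
                     arc_dist(pr$s, g$s_center, l$path$total) <=
                     g$width_mm / 2))
      }
    }
  }
  stop("unknown gap id: ", id)
}

#' Non-ablated nodes enclosed by the PVI rings
#'
#' The antral tissue between a PV sleeve and its encircling lesion is
#' isolated together with the veins; analyses of the "intra-PV"
#' compartment therefore include it. Enclosure is tested against the
#' ring centerline (distance to the PV-pair axis below the ring radius).
#'
#' @param mesh An `atrial_mesh`.
#' @param lesions A `lesion_set` containing ring lesions.
#' @return Node ids strictly inside a ring and not ablated.
#' @export
ring_interior_nodes <- function(mesh, lesions) {
  inside <- logical(nrow(mesh$nodes))
  for (l in lesions$lesions) {
    if (l$type != "ring") next
    ctrs <- mesh$pv_centers[l$pair, , drop = FALSE]
    ord <- order(ctrs[, 2])
    c_lo <- ctrs[ord[1], ]
    c_hi <- ctrs[ord[2], ]
    # distance to the vertical segment joining the pair centers
    dy <- pmin(pmax(mesh$nodes[, 2], c_lo[2]), c_hi[2])
    d <- sqrt((mesh$nodes[, 1] - c_lo[1])^2 + (mesh$nodes[, 2] - dy)^2)
    inside <- inside | d < l$radius
  }
  which(inside & mesh$tissue != "ablated")
}

#' Intra-PV and extra-PV node compartments
#'
#' @param mesh An `atrial_mesh`.
#' @param lesions Optional `lesion_set`; with ring lesions present the
#'   intra-PV compartment includes the enclosed antrum.
#' @return List with `intra` and `extra` node-id vectors (non-ablated).
#' @export
pv_compartments <- function(mesh, lesions = NULL) {
  pv <- which(startsWith(mesh$region, "pv") & mesh$tissue != "ablated")
  if (!is.null(lesions)) pv <- union(pv, ring_interior_nodes(mesh, lesions))
  all_ok <- which(mesh$tissue != "ablated")
  list(intra = sort(pv), extra = setdiff(all_ok, pv))
}

# gap center coordinates and local path direction, for analysis
gap_geometry <- function(lesions, id) {
  for (l in lesions$lesions) {
    if (l$type != "ring") next
    for (g in l$gaps) {
      if (g$id == id) {
        j <- which.min(arc_dist(l$path$s, g$s_center, l$path$total))
        return(list(center = l$path$pts[j, ], ring = l,
                    s_center = g$s_center, width_mm = g$width_mm))
      }
    }
  }
  stop("unknown gap id: ", id)
}

#' @export
print.lesion_set <- function(x, ...) {
  for (l in x$lesions) {
    if (l$type == "ring") {
      ng <- length(l$gaps)
      nf <- sum(vapply(l$gaps, `[[`, logical(1), "filled"))
      cat("ring around", paste(l$pair, collapse = "+"),
          sprintf("(radius %.1f mm, width %.1f mm, %d gap(s), %d filled)\n",
                  l$radius, l$width_mm, ng, nf))
    } else {
      cat(sprintf("focal disc at node %d (radius %.1f mm)\n",
                  l$center_node, l$radius_mm))
    }
  }
  invisible(x)
}
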