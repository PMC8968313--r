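# Mesh I/O in legacy ASCII VTK polydata with named per-node attributes:
# region (int), tissue_label (int), fiber (vectors). The title line
# carries the generator metadata needed to rebuild lesion sets
# (PV centers/radius, sheet size) as key=value pairs.

.region_codes <- c(la_body = 0L, pv1 = 1L, pv2 = 2L, pv3 = 3L, pv4 = 4L,
                   boundary = 5L)
.tissue_codes <- c(normal = 0L, fibrotic = 1L, ablated = 2L)

#' Write a mesh to legacy ASCII VTK polydata
#'
#' Coordinates, triangles, and the per-node attributes `region`,
#' `tissue_label`, and `fiber` round-trip losslessly through
#' [read_vtk_mesh()]. Additional per-node scalar fields (e.g. a DF map)
#' can be attached via `extra_scalars`.
#'
#' @param mesh An `atrial_mesh`.
#' @param path Output file path.
#' @param extra_scalars Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, extra_scalars = NULL) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$triangles)
  meta <- sprintf(
    "atrialwave w=%.6g h=%.6g r=%.6g edge=%.6g cx=%s cy=%s",
    mesh$width_mm, mesh$height_mm, mesh$pv_radius_mm, mesh$target_edge_um,
    paste(sprintf("%.6g", mesh$pv_centers[, 1]), collapse = ","),
    paste(sprintf("%.6g", mesh$pv_centers[, 2]), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", meta, "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]),
             con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L),
             con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(.region_codes[mesh$region]), con)
  writeLines(c("SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(.tissue_codes[mesh$tissue]), con)
  writeLines("VECTORS fiber double", con)
  writeLines(sprintf("%.17g %.17g 0", mesh$fibers[, 1], mesh$fibers[, 2]),
             con)
  for (nm in names(extra_scalars)) {
    v <- extra_scalars[[nm]]
    stopifnot(length(v) == n)
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", v), con)
  }
  invisible(path)
}

#' Read a mesh from legacy ASCII VTK polydata
#'
#' Parses files written by [write_vtk_mesh()] (and compatible polydata
#' with triangle cells). A missing `tissue_label` attribute defaults to
#' `normal` with a warning; triangles referencing nonexistent nodes are a
#' parse error.
#'
#' @param path Input file path.
#' @return An `atrial_mesh`. Extra scalar fields, if present, are
#'   attached as an `extra` element.
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  perr <- function(i, msg) stop("VTK parse error at line ", i, ": ", msg)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    perr(1, "not a legacy VTK file")
  title <- lines[2]
  i <- grep("^POINTS ", lines)[1]
  if (is.na(i)) perr(0, "no POINTS section")
  n <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  pts <- matrix(scan(text = lines[(i + 1):(i + n)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  if (nrow(pts) != n) perr(i, "wrong number of point rows")
  j <- grep("^POLYGONS ", lines)[1]
  if (is.na(j)) perr(0, "no POLYGONS section")
  m <- as.integer(strsplit(lines[j], "\\s+")[[1]][2])
  poly <- matrix(scan(text = lines[(j + 1):(j + m)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)
  if (any(poly[, 1] != 3)) perr(j, "non-triangle polygon")
  tri <- poly[, 2:4, drop = FALSE] + 1L
  if (any(tri < 1) || any(tri > n))
    perr(j, "triangle references a nonexistent node")
  storage.mode(tri) <- "integer"

  get_scalar <- function(name) {
    k <- grep(paste0("^SCALARS ", name, " "), lines)[1]
    if (is.na(k)) return(NULL)
    as.numeric(lines[(k + 2):(k + 1 + n)])
  }
  region_code <- get_scalar("region")
  region <- if (is.null(region_code)) rep("la_body", n) else
    names(.region_codes)[match(as.integer(region_code), .region_codes)]
  tissue_code <- get_scalar("tissue_label")
  if (is.null(tissue_code)) {
    warning("no tissue_label attribute; defaulting all nodes to 'normal'")
    tissue <- rep("normal", n)
  } else {
    tissue <- names(.tissue_codes)[match(as.integer(tissue_code),
                                         .tissue_codes)]
  }
  k <- grep("^VECTORS fiber ", lines)[1]
  fibers <- if (is.na(k)) cbind(rep(1, n), rep(0, n)) else
    matrix(scan(text = lines[(k + 1):(k + n)], quiet = TRUE),
           ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]

  kv <- function(key, default = NA_real_) {
    mt <- regmatches(title, regexec(paste0(key, "=([-0-9.eE,+]+)"), title))
    if (!length(mt[[1]])) return(default)
    as.numeric(strsplit(mt[[1]][2], ",")[[1]])
  }
  cx <- kv("cx")
  cy <- kv("cy")
  pv_centers <- if (any(is.na(cx))) {
    matrix(NA_real_, 4, 2, dimnames = list(paste0("pv", 1:4),
                                           c("x", "y")))
  } else {
    matrix(c(cx, cy), ncol = 2, dimnames = list(paste0("pv", 1:4),
                                                c("x", "y")))
  }

  # any remaining scalar fields
  extra <- list()
  for (k in grep("^SCALARS ", lines)) {
    nm <- strsplit(lines[k], "\\s+")[[1]][2]
    if (!nm %in% c("region", "tissue_label"))
      extra[[nm]] <- as.numeric(lines[(k + 2):(k + 1 + n)])
  }

  mesh <- structure(list(
    nodes = pts[, 1:2, drop = FALSE], triangles = tri,
    region = region, tissue = tissue, fibers = fibers,
    pv_centers = pv_centers,
    pv_radius_mm = kv("r")[1],
    pv_pairs = list(left = c("pv1", "pv2"), right = c("pv3", "pv4")),
    width_mm = kv("w")[1], height_mm = kv("h")[1],
    target_edge_um = kv("edge")[1], seed = NA_integer_),
    class = "atrial_mesh")
  es <- edge_length_stats(mesh)
  mesh$edge_mean_um <- es$mean_um
  mesh$edge_sd_um <- es$sd_um
  if (length(extra)) mesh$extra <- extra
  mesh
}
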