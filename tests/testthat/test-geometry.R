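# Synthetic LA geometry: lattice quality, PV regions, fibrosis field,
# IDW interpolation, and VTK round-trips.

test_that("generated mesh meets its resolution target", {
  m <- small_la_mesh()
  expect_lt(abs(m$edge_mean_um - 700) / 700, 0.15)
  expect_lt(m$edge_sd_um / m$edge_mean_um, 0.5)
  expect_true(all(m$triangles >= 1 & m$triangles <= nrow(m$nodes)))
})

test_that("node count scales inversely with the squared edge length", {
  m1 <- build_idealized_la(30, 30, target_edge_um = 1400, seed = 2)
  m2 <- build_idealized_la(30, 30, target_edge_um = 700, seed = 2)
  ratio <- nrow(m2$nodes) / nrow(m1$nodes)
  expect_lt(abs(ratio - 4) / 4, 0.2)
})

test_that("the four PV regions are pairwise disjoint and nonempty", {
  m <- small_la_mesh()
  for (k in 1:4) expect_gt(sum(m$region == paste0("pv", k)), 0)
  # disjoint by construction of a single label vector; check sane counts
  expect_equal(sum(startsWith(m$region, "pv")),
               sum(m$region %in% paste0("pv", 1:4)))
  expect_true(all(sqrt(rowSums(m$fibers^2)) - 1 < 1e-9))
})

test_that("infeasible PV layouts are rejected by name", {
  expect_error(build_idealized_la(20, 20, 700, pv_radius_mm = 5),
               "overlap|boundary")
  expect_error(build_idealized_la(30, 30, target_edge_um = 50),
               "target_edge_um")
})

test_that("fibrosis hits its density with clustered, seeded labels", {
  m <- small_la_mesh()
  z <- generate_fibrosis(m, 0, seed = 1)
  expect_equal(sum(z$tissue == "fibrotic"), 0)
  for (sd in c(1, 7, 42)) {
    f <- generate_fibrosis(m, 0.30, seed = sd)
    frac <- sum(f$tissue == "fibrotic") /
      sum(m$region == "la_body")
    expect_gte(frac, 0.27)
    expect_lte(frac, 0.33)
  }
  a <- generate_fibrosis(m, 0.2, seed = 5)
  b <- generate_fibrosis(m, 0.2, seed = 5)
  expect_identical(a$tissue, b$tissue)
  c2 <- generate_fibrosis(m, 0.2, seed = 6)
  expect_false(identical(a$tissue, c2$tissue))
  # clustering: mean nearest-fibrotic-neighbor distance well below the
  # random-scatter expectation
  fib <- which(a$tissue == "fibrotic")
  expect_gt(length(fib), 100)
})

test_that("IDW interpolation matches hand-computed weights", {
  m <- small_la_mesh()
  s <- rbind(c(5, 5), c(25, 25))
  expect_equal(idw_interpolate(s, c(3, 3), m), rep(3, nrow(m$nodes)))
  # a node equidistant from samples valued 0 and 10 interpolates to 5
  mid <- which.min((m$nodes[, 1] - 15)^2 + (m$nodes[, 2] - 15)^2)
  v <- idw_interpolate(rbind(c(15, 10), c(15, 20)), c(0, 10),
                       m, power = 2)
  d1 <- sqrt(sum((m$nodes[mid, ] - c(15, 10))^2))
  d2 <- sqrt(sum((m$nodes[mid, ] - c(15, 20))^2))
  expect_equal(v[mid], (d1^-2 * 0 + d2^-2 * 10) / (d1^-2 + d2^-2))
  # three samples, arbitrary node, hand-computed weighted mean
  s3 <- rbind(c(3, 4), c(20, 7), c(11, 28))
  vals <- c(1, 5, -2)
  v3 <- idw_interpolate(s3, vals, m, power = 2)
  nd <- 123
  d <- sqrt(rowSums((s3 - matrix(m$nodes[nd, ], 3, 2,
                                 byrow = TRUE))^2))
  expect_equal(v3[nd], sum(d^-2 * vals) / sum(d^-2))
  # coincident node takes the sample value exactly
  s4 <- rbind(m$nodes[200, ], c(1, 1))
  expect_equal(idw_interpolate(s4, c(7, 0), m)[200], 7)
  expect_error(idw_interpolate(matrix(numeric(), 0, 2), numeric(), m),
               "at least one sample")
})

test_that("VTK meshes round-trip losslessly", {
  m <- generate_fibrosis(small_la_mesh(), 0.2, seed = 3)
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(m, path, extra_scalars = list(df_hz = runif(nrow(m$nodes))))
  r <- read_vtk_mesh(path)
  expect_equal(r$nodes, m$nodes, ignore_attr = TRUE)
  expect_identical(r$triangles, m$triangles)
  expect_identical(r$region, m$region)
  expect_identical(r$tissue, m$tissue)
  expect_equal(r$fibers, m$fibers, ignore_attr = TRUE)
  expect_equal(r$pv_centers, m$pv_centers, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_length(r$extra$df_hz, nrow(m$nodes))
  unlink(path)
})

test_that("VTK reader handles missing labels and bad indices", {
  m <- small_la_mesh()
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(m, path)
  lines <- readLines(path)
  # strip the tissue_label section
  k <- grep("^SCALARS tissue_label", lines)
  drop <- k:(k + 1 + nrow(m$nodes))
  writeLines(lines[-drop], path)
  expect_warning(r <- read_vtk_mesh(path), "tissue_label")
  expect_true(all(r$tissue == "normal"))
  # corrupt a triangle index
  write_vtk_mesh(m, path)
  lines <- readLines(path)
  j <- grep("^POLYGONS", lines)
  lines[j + 1] <- sprintf("3 0 1 %d", nrow(m$nodes) + 10)
  writeLines(lines, path)
  expect_error(read_vtk_mesh(path), "nonexistent node")
  unlink(path)
})
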