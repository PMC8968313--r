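# PVI lesion sets: isolation, gaps, gap filling, focal lesions. The
# connectivity oracle is an independent BFS (helper), not the package's
# own graph code.

test_that("CPVI disconnects the PV compartment from the body", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = FALSE)
  mc <- apply_lesions(m, les)
  comp <- pv_compartments(mc, les)
  expect_false(bfs_connected(mc, comp$intra, comp$extra))
  # package graph agrees with the BFS oracle
  expect_false(regions_connected(mc, comp$intra, comp$extra))
})

test_that("gapped PVI conducts only through its gap corridors", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = TRUE)
  expect_setequal(gap_ids(les), c("left_ant", "left_post", "right_ant",
                                  "right_post"))
  mg <- apply_lesions(m, les)
  comp <- pv_compartments(mg, les)
  expect_true(bfs_connected(mg, comp$intra, comp$extra))
  # removing the four corridors severs the connection
  m2 <- mg
  for (id in gap_ids(les))
    m2$tissue[gap_corridor_nodes(m2, les, id)] <- "ablated"
  expect_false(bfs_connected(m2, comp$intra, comp$extra))
})

test_that("gap corridors measure the nominal 2-mm width", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = TRUE, gap_width_mm = 2)
  edge_mm <- m$edge_mean_um / 1000
  for (id in gap_ids(les)) {
    nodes <- gap_corridor_nodes(m, les, id)
    expect_gt(length(nodes), 0)
    # arc-wise extent, measured as twice the largest wrapped arc
    # distance of any corridor node from the gap center
    xy <- m$nodes[nodes, , drop = FALSE]
    geo <- atrialwave:::gap_geometry(les, id)
    pr <- atrialwave:::path_project(xy, geo$ring$path)
    arc <- 2 * max(atrialwave:::arc_dist(pr$s, geo$s_center,
                                         geo$ring$path$total))
    expect_lt(abs(arc - 2), edge_mm + 1e-9)
  }
})

test_that("filling all gaps reproduces the complete PVI node set", {
  m <- small_la_mesh()
  cpvi <- make_pvi_lesions(m, with_gaps = FALSE)
  gap <- make_pvi_lesions(m, with_gaps = TRUE)
  filled <- fill_gaps(gap, gap_ids(gap))
  expect_identical(
    which(apply_lesions(m, filled)$tissue == "ablated"),
    which(apply_lesions(m, cpvi)$tissue == "ablated"))
  expect_identical(fill_gaps(gap, character()), gap)
  expect_error(fill_gaps(gap, "no_such_gap"), "unknown gap id")
  # filling 2 of 4 keeps PV-body conduction through the remainder
  half <- fill_gaps(gap, c("left_ant", "right_post"))
  mh <- apply_lesions(m, half)
  comp <- pv_compartments(mh, half)
  expect_true(bfs_connected(mh, comp$intra, comp$extra))
})

test_that("lesion application is idempotent and local", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = TRUE)
  once <- apply_lesions(m, les)
  twice <- apply_lesions(once, les)
  expect_identical(once$tissue, twice$tissue)
  untouched <- which(once$tissue != "ablated")
  expect_identical(once$tissue[untouched], m$tissue[untouched])
  expect_identical(once$region, m$region)
})

test_that("every ring band is edge-connected (no holes)", {
  m <- small_la_mesh()
  les <- make_pvi_lesions(m, with_gaps = FALSE)
  mc <- apply_lesions(m, les)
  abl <- which(mc$tissue == "ablated")
  # connectivity of the ablated band itself, per ring, via BFS on an
  # inverted mesh (treat non-ablated as removed)
  inv <- mc
  inv$tissue <- ifelse(mc$tissue == "ablated", "normal", "ablated")
  comp <- bfs_components(inv)
  expect_equal(length(unique(na.omit(comp[abl]))), 2)  # one per ring
})

test_that("focal lesions ablate discs that grow quadratically", {
  m <- small_la_mesh()
  ctr <- which.min((m$nodes[, 1] - 15)^2 + (m$nodes[, 2] - 15)^2)
  edge_mm <- m$edge_mean_um / 1000
  f1 <- apply_lesions(m, make_focal_lesion(m, ctr, edge_mm))
  expect_gte(sum(f1$tissue == "ablated"), 1)
  n2 <- sum(apply_lesions(m, make_focal_lesion(m, ctr, 2))$tissue ==
            "ablated")
  n4 <- sum(apply_lesions(m, make_focal_lesion(m, ctr, 4))$tissue ==
            "ablated")
  expect_gt(n4 / n2, 2.8)
  expect_lt(n4 / n2, 5.5)
  expect_error(make_focal_lesion(m, ctr, 0.1), "mean edge")
  # idempotent even when centered on an ablated node
  again <- apply_lesions(f1, make_focal_lesion(f1, ctr, edge_mm))
  expect_identical(sum(again$tissue == "ablated"),
                   sum(f1$tissue == "ablated"))
})
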