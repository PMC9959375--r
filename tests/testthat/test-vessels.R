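test_that("skeletonization preserves component topology", {
  m <- rasterize_tube_tree(
    list(tube_segment(c(16, 16, 5), c(16, 16, 105), 5)),
    c(32, 32, 111), sp_iso(1)
  )
  sk <- skeletonize(m)
  expect_equal(max(villomorph:::cpp_label26(sk$voxels)), 1)
  # two disjoint tubes -> two skeleton components
  m2 <- rasterize_tube_tree(
    list(tube_segment(c(8, 8, 5), c(8, 8, 70), 3),
         tube_segment(c(24, 24, 5), c(24, 24, 70), 3)),
    c(32, 32, 76), sp_iso(1)
  )
  expect_equal(max(villomorph:::cpp_label26(skeletonize(m2)$voxels)), 2)
  expect_error(skeletonize(binary_mask(array(FALSE, c(4, 4, 4)), sp_iso(1))),
               "empty")
})

test_that("a solid torus skeletonizes to a closed cycle", {
  tor <- tube_arc(center = c(16, 40, 40), u = c(0, 1, 0), v = c(0, 0, 1),
                  arc_radius = 25, theta = c(0, 2 * pi - 1e-9), radius = 4)
  m <- rasterize_tube_tree(list(tor), c(32, 80, 80), sp_iso(1))
  g <- build_network(skeletonize(m))
  # a cycle: either a closed-loop edge or edges >= nodes in the component
  has_loop <- any(g$edges$from == g$edges$to & g$edges$arc_length_um > 50)
  expect_true(has_loop || nrow(g$edges) >= nrow(g$nodes))
  # loop tortuosity is undefined and excluded, counted separately
  mt <- mean_tortuosity(g)
  expect_gte(mt$n_undefined, 1)
})

test_that("a straight tube yields one edge, two endpoints, unit tortuosity", {
  g <- straight_tube_graph()
  expect_equal(sum(g$nodes$kind == "branchpoint"), 0)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(segment_tortuosity(g$edges[1, ]), 1, tolerance = 0.05)
  expect_equal(branchpoint_density(g), 0)
})

test_that("a symmetric Y-tube yields one branchpoint, three endpoints, three edges", {
  g <- y_tube_graph()
  expect_equal(sum(g$nodes$kind == "branchpoint"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(g$edges), 3)
  # branchpoint density ~ 1 / total length
  expect_equal(branchpoint_density(g), 1 / sum(g$edges$arc_length_um))
})

test_that("arc tortuosity matches the analytic arc/chord ratios", {
  half <- tube_arc(center = c(12, 8, 70), u = c(0, 1, 0), v = c(0, 0, 1),
                   arc_radius = 60, theta = c(-pi / 2, pi / 2), radius = 2.5)
  mH <- rasterize_tube_tree(list(half), c(24, 80, 145), sp_iso(1))
  gH <- build_network(skeletonize(mH))
  expect_equal(nrow(gH$edges), 1)
  expect_equal(segment_tortuosity(gH$edges[1, ]), pi / 2, tolerance = 0.05 * pi / 2)

  quarter <- tube_arc(center = c(12, 8, 10), u = c(0, 1, 0), v = c(0, 0, 1),
                      arc_radius = 60, theta = c(0, pi / 2), radius = 2.5)
  mQ <- rasterize_tube_tree(list(quarter), c(24, 80, 80), sp_iso(1))
  gQ <- build_network(skeletonize(mQ))
  expect_equal(segment_tortuosity(gQ$edges[1, ]), pi / (2 * sqrt(2)),
               tolerance = 0.05 * pi / (2 * sqrt(2)))
})

test_that("tortuosity is at least 1 for every reported edge", {
  for (g in list(straight_tube_graph(), y_tube_graph())) {
    tort <- g$edges$tortuosity
    expect_true(all(is.na(tort) | tort >= 1 - 1e-9))
  }
})

test_that("diameters are recovered from the distance transform", {
  g <- straight_tube_graph()
  expect_equal(g$edges$mean_diameter_um, 10, tolerance = 0.11)
  ds <- diameter_stats(g)
  expect_lt(ds$per_edge$cv_diameter[1], 0.1)

  # linearly tapering tube 8 -> 2 um radius: minimum diameter ~ 4 um
  segs <- lapply(1:20, function(i) {
    tube_segment(c(16, 16, 5 + (i - 1) * 5), c(16, 16, 5 + i * 5),
                 8 - 6 * (i - 0.5) / 20)
  })
  mt <- rasterize_tube_tree(segs, c(32, 32, 111), sp_iso(1))
  gt <- build_network(skeletonize(mt))
  expect_lt(abs(diameter_stats(gt)$network$min_diameter_um - 4), 1)

  # two disjoint tubes: per-edge means match their planted radii
  m2 <- rasterize_tube_tree(
    list(tube_segment(c(10, 10, 5), c(10, 10, 80), 3),
         tube_segment(c(28, 28, 5), c(28, 28, 80), 6)),
    c(40, 40, 86), sp_iso(1)
  )
  g2 <- build_network(skeletonize(m2))
  expect_equal(sort(g2$edges$mean_diameter_um), c(6, 12), tolerance = 0.15)
})

test_that("network length is additive over disjoint components", {
  mk <- function(prims, shape) {
    build_network(skeletonize(rasterize_tube_tree(prims, shape, sp_iso(1))))
  }
  a <- mk(list(tube_segment(c(10, 10, 5), c(10, 10, 80), 3)), c(40, 40, 86))
  b <- mk(list(tube_segment(c(28, 28, 5), c(28, 28, 80), 3)), c(40, 40, 86))
  ab <- mk(list(tube_segment(c(10, 10, 5), c(10, 10, 80), 3),
                tube_segment(c(28, 28, 5), c(28, 28, 80), 3)), c(40, 40, 86))
  expect_equal(sum(ab$edges$arc_length_um),
               sum(a$edges$arc_length_um) + sum(b$edges$arc_length_um),
               tolerance = 1e-6)
})

test_that("90-degree rotation leaves counts and arc lengths unchanged", {
  tr <- tube_random_tree(3, seed = 5)
  m <- rasterize_tube_tree(tr$primitives, c(72, 172, 172), sp_iso(1),
                           check_bounds = FALSE)
  g0 <- build_network(skeletonize(m))
  rot <- binary_mask(aperm(m$data, c(1, 3, 2))[, , dim(m$data)[2]:1],
                     m$spacing) # 90 degrees about z
  g1 <- build_network(skeletonize(rot))
  expect_equal(sum(g1$nodes$kind == "branchpoint"),
               sum(g0$nodes$kind == "branchpoint"))
  expect_equal(sort(g1$edges$arc_length_um), sort(g0$edges$arc_length_um),
               tolerance = 0.05)
})

test_that("junction counts are recovered on random tree phantoms", {
  errs <- sapply(1:20, function(s) {
    nj <- 2 + (s %% 5)
    tr <- tube_random_tree(nj, seed = s)
    m <- rasterize_tube_tree(tr$primitives, c(72, 172, 172), sp_iso(1),
                             check_bounds = FALSE)
    g <- build_network(skeletonize(m))
    sum(g$nodes$kind == "branchpoint") - nj
  })
  expect_gte(sum(errs == 0), 18)
  expect_lte(max(abs(errs)), 1)
})

test_that("anisotropic masks give the same physical network metrics", {
  # same physical Y geometry sampled at 1 um and at (1.5, 0.7, 0.7) um
  prims <- list(tube_y(c(20, 20, 60),
                       rbind(c(20, 20, 5), c(20, 45, 110), c(20, 5, 100)), 5))
  g_iso <- y_tube_graph()
  spA <- voxel_spacing(1.5, 0.7, 0.7)
  shapeA <- c(round(40 / 1.5), round(52 / 0.7), round(116 / 0.7)) + 1L
  mA <- rasterize_tube_tree(prims, shapeA, spA, check_bounds = FALSE)
  gA <- build_network(skeletonize(mA))
  expect_equal(sum(gA$nodes$kind == "branchpoint"), 1)
  expect_equal(sum(gA$edges$arc_length_um), sum(g_iso$edges$arc_length_um),
               tolerance = 0.05)
})

test_that("network export formats are readable and consistent", {
  g <- y_tube_graph()
  pn <- withr::local_tempfile(fileext = ".csv")
  pe <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(g, pn, pe)
  nodes <- read.csv(pn)
  edges <- read.csv(pe)
  expect_equal(nrow(nodes), nrow(g$nodes))
  expect_equal(nrow(edges), nrow(g$edges))
  pv <- withr::local_tempfile(fileext = ".vtk")
  write_network_vtk(g, pv)
  vtk <- readLines(pv, warn = FALSE)
  expect_equal(vtk[1], "# vtk DataFile Version 3.0")
  npts <- sum(vapply(g$polylines, nrow, integer(1)))
  expect_true(any(grepl(sprintf("POINTS %d float", npts), vtk)))
  expect_true(any(grepl("SCALARS tortuosity", vtk)))
})

test_that("tidy and glance summarise a network", {
  g <- y_tube_graph()
  td <- generics::tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- generics::glance(g)
  expect_equal(gl$n_branchpoints, 1)
  expect_equal(gl$n_edges, 3)
  expect_gt(gl$total_length_um, 100)
})
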