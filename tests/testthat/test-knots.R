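test_that("dbscan separates a chain cluster from an outlier", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(10, 0, 0))
  cl <- dbscan_cluster(pts, eps = 1.5, min_pts = 2)
  expect_equal(cl, dbscan_brute(pts, 1.5, 2)) # brute-force oracle agrees
  expect_equal(cl[1:3], rep(cl[1], 3))
  expect_gt(cl[1], 0)
  expect_equal(cl[4], 0)
})

test_that("dbscan degenerate inputs behave", {
  same <- matrix(rep(c(1, 2, 3), 6), ncol = 3, byrow = TRUE)
  expect_equal(dbscan_cluster(same, eps = 0.5, min_pts = 6), rep(1L, 6))
  expect_equal(dbscan_cluster(matrix(numeric(0), ncol = 3), 1, 1), integer(0))
  single <- matrix(c(0, 0, 0), ncol = 3)
  expect_equal(dbscan_cluster(single, 1, 1), 1L)
})

test_that("dbscan matches the brute-force reference on random instances", {
  for (s in 1:15) {
    set.seed(s)
    n <- sample(20:200, 1)
    # mixture of tight clusters and background points
    k <- sample(2:5, 1)
    centres <- matrix(runif(3 * k, 0, 100), ncol = 3)
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      sweep(matrix(rnorm(3 * 15, sd = 3), ncol = 3), 2, centres[i, ], `+`)
    }))
    pts <- rbind(pts, matrix(runif(3 * n, 0, 100), ncol = 3))
    eps <- runif(1, 2, 8)
    min_pts <- sample(2:8, 1)
    a <- dbscan_cluster(pts, eps, min_pts)
    b <- dbscan_brute(pts, eps, min_pts)
    expect_identical(canonical_labels(a), canonical_labels(b))
  }
})

test_that("shape indices match the uniform-ellipsoid oracle", {
  cases <- list(
    list(axes = c(20, 10, 5), EI = 0.50, FI = 0.50),
    list(axes = c(20, 16, 4), EI = 0.80, FI = 0.25),
    list(axes = c(15, 15, 15), EI = 1.00, FI = 1.00)
  )
  for (cs in cases) {
    pts <- ellipsoid_cloud(cs$axes, n = 6000, seed = 42)
    shp <- knot_shape(pts)
    expect_lt(abs(shp$EI - cs$EI), 0.05)
    expect_lt(abs(shp$FI - cs$FI), 0.05)
    expect_true(shp$L1 >= shp$L2 && shp$L2 >= shp$L3 && shp$L3 > 0)
  }
})

test_that("EI and FI are invariant to rigid rotation and uniform scaling", {
  pts <- ellipsoid_cloud(c(18, 9, 4), n = 5000, seed = 7)
  base <- knot_shape(pts)
  for (s in 1:5) {
    R <- random_rotation_matrix(s)
    scale <- runif(1, 0.2, 5)
    tr <- scale * pts %*% t(R)
    rot <- knot_shape(tr)
    expect_equal(rot$EI, base$EI, tolerance = 1e-6)
    expect_equal(rot$FI, base$FI, tolerance = 1e-6)
    expect_equal(rot$L1 / base$L1, scale, tolerance = 1e-6)
  }
})

test_that("degenerate point sets raise a rank-deficiency error", {
  plane <- cbind(runif(50), runif(50), 0)
  expect_error(knot_shape(plane), "rank|coplanar")
  line <- cbind(seq_len(50), seq_len(50) * 2, seq_len(50) * 3)
  expect_error(knot_shape(line), "rank|collinear")
  expect_error(knot_shape(plane[1:3, ]), "at least 4")
})

test_that("knots are detected from the planted phantom with high membership F1", {
  q <- demo_quantified(42L)
  tr <- q$ph$truth
  kn <- detect_knots(q$rec, q$nuc, eps = 9, min_pts = 3, min_members = 10,
                     intensity_gate = 1.3)
  expect_equal(nrow(kn), 2)
  m <- match_detections(as.matrix(q$rec[, c("cz", "cy", "cx")]),
                        tr$nucleus_centres, 3)
  true_knot <- ifelse(m$nearest_dist <= 3,
                      tr$knot_membership[m$nearest_truth], 0L)
  det_knot <- rep(0L, nrow(q$rec))
  for (i in seq_len(nrow(kn))) {
    det_knot[q$rec$label %in% kn$member_labels[[i]]] <- i
  }
  tp <- sum(det_knot > 0 & true_knot > 0)
  fp <- sum(det_knot > 0 & true_knot == 0)
  fn <- sum(det_knot == 0 & true_knot > 0) +
    sum(!m$truth_matched & tr$knot_membership > 0)
  expect_gte(2 * tp / (2 * tp + fp + fn), 0.9)
})

test_that("a dispersed-only phantom yields no knots", {
  shape <- c(40L, 60L, 60L)
  tube <- list(tube_segment(c(20, 30, 3), c(20, 30, 56), 22))
  spec <- phantom_spec(shape, sp_iso(1), tube, n_nuclei = 60,
                       nucleus_radius = 3, noise_sigma = 0)
  villus <- rasterize_tube_tree(tube, shape, sp_iso(1))
  pl <- plant_nuclei(villus, spec, seed = 17)
  rec <- extract_nucleus_records(pl$labels)
  rec$mean_intensity <- 100
  kn <- detect_knots(rec, pl$labels, eps = 4, min_pts = 4, min_members = 10)
  expect_equal(nrow(kn), 0)
})

test_that("an elongated planted knot is detected as one knot", {
  shape <- c(80L, 100L, 100L)
  tube <- list(tube_segment(c(40, 50, 5), c(40, 50, 95), 35))
  spec <- phantom_spec(
    shape, sp_iso(1), tube, n_nuclei = 0, nucleus_radius = 3,
    knot_specs = list(list(centre = c(40, 30, 50), n_members = 15,
                           gain = 2, axes = c(24, 12, 6)))
  )
  villus <- rasterize_tube_tree(tube, shape, sp_iso(1))
  pl <- plant_nuclei(villus, spec, seed = 23)
  rec <- extract_nucleus_records(pl$labels)
  rec$mean_intensity <- 200
  kn <- detect_knots(rec, pl$labels, eps = 9, min_pts = 3, min_members = 10)
  expect_equal(nrow(kn), 1)
  expect_lt(kn$EI, 0.85) # clearly elongated
})

test_that("knot fraction arithmetic, additivity and monotonicity hold", {
  kn <- tibble::tibble(volume_um3 = c(1200, 800))
  expect_equal(knot_fraction(kn, 1e5), 2)
  expect_equal(knot_fraction(kn[0, ], 1e5), 0)
  expect_error(knot_fraction(kn, 0), "positive")
  # additive over disjoint knot sets
  expect_equal(knot_fraction(kn[1, ], 1e5) + knot_fraction(kn[2, ], 1e5),
               knot_fraction(kn, 1e5))
  # monotone in min_members: lowering the gate can only add knots
  q <- demo_quantified(42L)
  k10 <- detect_knots(q$rec, q$nuc, eps = 9, min_pts = 3, min_members = 10,
                      intensity_gate = 1.3)
  k6 <- detect_knots(q$rec, q$nuc, eps = 9, min_pts = 3, min_members = 6,
                     intensity_gate = 1.3)
  v <- mask_volume(q$ph$truth$villous_mask)
  expect_gte(knot_fraction(k6, v), knot_fraction(k10, v))
})

test_that("planted elongation is recovered on average across seeds", {
  shape <- c(80L, 100L, 100L)
  tube <- list(tube_segment(c(40, 50, 5), c(40, 50, 95), 35))
  classes <- list(round_ = c(12, 11, 10), elong = c(24, 12, 6))
  for (nm in names(classes)) {
    ax <- classes[[nm]]
    spec <- phantom_spec(
      shape, sp_iso(1), tube, n_nuclei = 0, nucleus_radius = 3,
      knot_specs = list(list(centre = c(40, 30, 50), n_members = 18,
                             gain = 2, axes = ax))
    )
    villus <- memo(paste0("shape_villus"),
                   rasterize_tube_tree(tube, shape, sp_iso(1)))
    res <- sapply(1:20, function(s) {
      pl <- plant_nuclei(villus, spec, seed = s)
      rec <- extract_nucleus_records(pl$labels)
      rec$mean_intensity <- 200
      kn <- detect_knots(rec, pl$labels, eps = 9, min_pts = 3,
                         min_members = 10)
      # per-seed oracle: shape of the full planted member voxel cloud
      vox <- which(pl$labels$data %in% which(pl$knot_membership > 0))
      pos <- villomorph:::voxel_to_um(arrayInd(vox, dim(pl$labels$data)),
                                      pl$labels$spacing)
      ei_truth <- knot_shape(pos)$EI
      c(ei_det = if (nrow(kn) == 1) kn$EI else NA_real_, ei_truth = ei_truth)
    })
    expect_lt(mean(abs(res["ei_det", ] - res["ei_truth", ]), na.rm = TRUE),
              0.1)
    expect_lt(mean(is.na(res["ei_det", ])), 0.25)
    # the two shape classes stay separated on the detected EI scale
    if (nm == "round_") round_med <- median(res["ei_det", ], na.rm = TRUE)
    if (nm == "elong") {
      expect_lt(median(res["ei_det", ], na.rm = TRUE), round_med - 0.2)
    }
  }
})
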