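test_that("3-D median filtering removes isolated outliers and reduces noise", {
  const <- image_stack(array(37, dim = c(1, 8, 8, 8)), sp_iso(1))
  expect_equal(denoise_median(const, 1)$data, const$data)

  hot <- array(0, dim = c(1, 9, 9, 9))
  hot[1, 5, 5, 5] <- 255
  st <- image_stack(hot, sp_iso(1))
  expect_equal(max(denoise_median(st, 1)$data), 0)

  set.seed(2)
  noise <- array(sample(0:255, 20^3, replace = TRUE), dim = c(1, 20, 20, 20))
  stn <- image_stack(noise, sp_iso(1))
  expect_lt(var(as.vector(denoise_median(stn, 1)$data)),
            var(as.vector(noise)))
})

test_that("threshold segmentation is exact on separable two-level data", {
  tube <- list(tube_segment(c(10, 16, 4), c(10, 16, 56), 7))
  planted <- rasterize_tube_tree(tube, c(21, 32, 61), sp_iso(1))
  arr <- array(10, dim = c(1, 21, 32, 61))
  arr[1, , , ][planted$data] <- 200
  st <- image_stack(arr, sp_iso(1))
  m <- segment_channel(st, 1, method = "otsu")
  expect_identical(m$data, planted$data)
})

test_that("small components are removed by the physical size filter", {
  arr <- array(0, dim = c(1, 20, 20, 40))
  arr[1, 8:12, 8:12, 5:25] <- 200 # main block, 2205 um^3
  speckles <- rbind(c(2, 2, 30), c(18, 3, 35), c(3, 18, 33), c(17, 17, 30),
                    c(10, 2, 38))
  for (i in seq_len(nrow(speckles))) {
    s <- speckles[i, ]
    arr[1, s[1] + 0:1, s[2] + 0:1, s[3] + 0:1] <- 200 # 8 um^3 each
  }
  st <- image_stack(arr, sp_iso(1))
  m_raw <- segment_channel(st, 1, method = 100)
  expect_equal(max(villomorph:::cpp_label26(m_raw$data)), 6)
  m <- segment_channel(st, 1, method = 100, min_size_um3 = 50)
  expect_equal(max(villomorph:::cpp_label26(m$data)), 1)
  expect_equal(sum(m$data), 5 * 5 * 21)
})

test_that("otsu on a constant channel is an explicit error", {
  st <- image_stack(array(42, dim = c(1, 6, 6, 6)), sp_iso(1))
  expect_error(segment_channel(st, 1, method = "otsu"), "degenerate|constant")
})

test_that("fixed-threshold masks are monotone in the threshold", {
  set.seed(4)
  arr <- array(sample(0:255, 16^3, replace = TRUE), dim = c(1, 16, 16, 16))
  st <- image_stack(arr, sp_iso(1))
  for (pair in list(c(50, 120), c(80, 200), c(10, 250))) {
    m1 <- segment_channel(st, 1, method = pair[1])
    m2 <- segment_channel(st, 1, method = pair[2])
    expect_true(all(!m2$data | m1$data)) # mask(t2) subset of mask(t1)
  }
})

test_that("villous segmentation of the noisy phantom overlaps the planted mask", {
  q <- demo_quantified(42L)
  vil <- segment_channel(q$den, "villi", min_size_um3 = 500, fill_holes = TRUE)
  expect_gte(dice_overlap(vil, q$ph$truth$villous_mask), 0.95)
})

test_that("well-separated spherical nuclei are segmented one-to-one", {
  shape <- c(40L, 60L, 60L)
  spec <- phantom_spec(shape, sp_iso(1),
                       tube_tree = list(tube_segment(c(20, 30, 3),
                                                     c(20, 30, 56), 25)),
                       n_nuclei = 0, nucleus_radius = 3, noise_sigma = 0)
  set.seed(31)
  centres <- as.matrix(expand.grid(z = c(12, 28), y = seq(10, 50, by = 10),
                                   x = seq(10, 50, by = 10)))[, c("z", "y", "x")]
  centres <- centres + matrix(runif(length(centres), -1, 1), nrow(centres))
  labs <- villomorph:::stamp_nuclei(centres, 3, shape, sp_iso(1))
  arr <- array(0, dim = c(1, shape))
  arr[1, , , ][labs > 0] <- 200
  st <- image_stack(arr, sp_iso(1), channel_names = "nuclei")
  nuc <- segment_nuclei_instances(st, "nuclei")
  expect_equal(n_labels(nuc), nrow(centres))
  rec <- extract_nucleus_records(nuc, st, "nuclei")
  m <- match_detections(as.matrix(rec[, c("cz", "cy", "cx")]), centres, 3)
  expect_true(all(m$nearest_dist < 1)) # centroid error below one voxel
})

test_that("two overlapping spheres are split into two instances", {
  shape <- c(24L, 24L, 30L)
  centres <- rbind(c(12, 12, 12), c(12, 12, 12 + 1.7 * 4)) # 30% radius overlap
  labs <- villomorph:::stamp_nuclei(centres, 4, shape, sp_iso(1))
  arr <- array(0, dim = c(1, shape))
  arr[1, , , ][labs > 0] <- 200
  st <- image_stack(arr, sp_iso(1), channel_names = "nuclei")
  nuc <- segment_nuclei_instances(st, "nuclei", sigma_range = c(1.6, 2.4),
                                  min_distance = 3)
  expect_equal(n_labels(nuc), 2)
})

test_that("an empty nuclei channel yields an empty label map with a warning", {
  st <- image_stack(array(0, dim = c(1, 10, 10, 10)), sp_iso(1),
                    channel_names = "nuclei")
  expect_warning(nuc <- segment_nuclei_instances(st, "nuclei"), "empty|seeds")
  expect_equal(n_labels(nuc), 0)
})

test_that("nucleus records report exact volumes and one row per label", {
  lab <- array(0L, dim = c(5, 5, 5))
  lab[2, 2, 2] <- 1L
  lab[c(1, 3), 4, 4] <- 2L
  lab[4, 1:3, 1] <- 3L
  lab[5, 5, 1:2] <- 4L
  lm <- label_map(lab, sp_iso(1))
  rec <- extract_nucleus_records(lm)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$volume_um3[rec$label == 1], 1)
  expect_equal(rec$volume_um3[rec$label == 3], 3)
  lm7 <- label_map(array(c(rep(1L, 7), rep(0L, 20)), dim = c(3, 3, 3)),
                   sp_iso(1))
  expect_equal(extract_nucleus_records(lm7)$volume_um3, 7)
  # anisotropic voxel volume
  lm_a <- label_map(array(c(rep(1L, 7), rep(0L, 20)), dim = c(3, 3, 3)),
                    voxel_spacing(1.5, 0.7, 0.7))
  expect_equal(extract_nucleus_records(lm_a)$volume_um3, 7 * 0.735)
})

test_that("planted phantom centroids are recovered with sub-radius error", {
  q <- demo_quantified(42L)
  m <- match_detections(as.matrix(q$rec[, c("cz", "cy", "cx")]),
                        q$ph$truth$nucleus_centres, 3)
  expect_lt(median(m$nearest_dist), 3 / 2)
})

test_that("physical outputs are invariant to voxel-size refinement", {
  tube <- list(tube_segment(c(20, 20, 4), c(20, 20, 56), 12))
  mk <- function(d) {
    shape <- round(c(40, 40, 60) / d) + 1L
    planted <- rasterize_tube_tree(tube, shape, sp_iso(d), check_bounds = FALSE)
    arr <- array(5, dim = c(1, shape))
    arr[1, , , ][planted$data] <- 200
    st <- image_stack(arr, sp_iso(d))
    segment_channel(st, 1, method = "otsu")
  }
  v1 <- mask_volume(mk(1))
  v2 <- mask_volume(mk(0.5))
  expect_equal(v2 / v1, 1, tolerance = 0.05)
})
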