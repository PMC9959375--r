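test_that("rasterized cylinder volume matches the analytic value", {
  m <- rasterize_tube_tree(
    list(tube_segment(c(15, 15, 5), c(15, 15, 105), 10)),
    shape = c(31, 31, 111), spacing = sp_iso(1)
  )
  expect_equal(sum(m$data), pi * 10^2 * 100, tolerance = 0.02)
})

test_that("rasterization handles empty input and disjoint unions", {
  m0 <- rasterize_tube_tree(list(), c(10, 10, 10), sp_iso(1))
  expect_false(any(m0$data))
  m2 <- rasterize_tube_tree(
    list(tube_segment(c(8, 8, 5), c(8, 8, 55), 4),
         tube_segment(c(24, 24, 5), c(24, 24, 55), 4)),
    shape = c(32, 32, 61), spacing = sp_iso(1)
  )
  lab <- villomorph:::cpp_label26(m2$data)
  expect_equal(max(lab), 2)
  expect_error(
    rasterize_tube_tree(list(tube_segment(c(5, 5, -20), c(5, 5, 5), 2)),
                        c(10, 10, 10), sp_iso(1)),
    "outside"
  )
})

test_that("primitive volumes converge to analytic values as resolution grows", {
  vol_err <- function(d) {
    m <- rasterize_tube_tree(
      list(tube_segment(c(12, 12, 3), c(12, 12, 43), 8)),
      shape = round(c(24, 24, 46) / d), spacing = sp_iso(d),
      check_bounds = FALSE
    )
    abs(mask_volume(m) - pi * 64 * 40) / (pi * 64 * 40)
  }
  e_coarse <- vol_err(1)
  e_fine <- vol_err(0.5)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 0.01)
})

test_that("nucleus planting honours the shell, separation and determinism", {
  villus <- rasterize_tube_tree(
    list(tube_segment(c(25, 25, 5), c(25, 25, 95), 16)),
    shape = c(50, 50, 101), spacing = sp_iso(1)
  )
  spec <- phantom_spec(
    shape = c(50L, 50L, 101L), spacing = sp_iso(1),
    tube_tree = list(tube_segment(c(25, 25, 5), c(25, 25, 95), 16)),
    n_nuclei = 50, nucleus_radius = 3
  )
  pl <- plant_nuclei(villus, spec, seed = 5)
  expect_equal(n_labels(pl$labels), 50)
  expect_equal(nrow(pl$centres), 50)
  # all centres in the shell: inside mask, within 2r of the boundary
  sp <- unclass(villus$spacing)
  din <- villomorph:::cpp_edt(villus$data, sp[["dz"]], sp[["dy"]], sp[["dx"]])
  vi <- villomorph:::um_to_voxel(pl$centres, villus$spacing)
  expect_true(all(villus$data[vi]))
  expect_true(all(din[vi] <= 2 * 3 + 1)) # +1 voxel jitter allowance
  # minimum separation 1.5 r between non-knot nuclei
  d <- as.matrix(dist(pl$centres))
  diag(d) <- Inf
  expect_gte(min(d), 1.5 * 3 - 1e-9)
  # determinism
  pl2 <- plant_nuclei(villus, spec, seed = 5)
  expect_identical(pl$labels$data, pl2$labels$data)
  # an impossible request errors instead of silently under-filling
  tiny_spec <- phantom_spec(
    shape = c(50L, 50L, 101L), spacing = sp_iso(1),
    tube_tree = spec$tube_tree, n_nuclei = 100000, nucleus_radius = 3
  )
  expect_error(plant_nuclei(villus, tiny_spec, seed = 1), "draws")
})

test_that("planted knot covariance axes are recovered from member centres", {
  villus <- rasterize_tube_tree(
    list(tube_segment(c(50, 50, 5), c(50, 50, 115), 40)),
    shape = c(100, 100, 121), spacing = sp_iso(1)
  )
  spec <- phantom_spec(
    shape = c(100L, 100L, 121L), spacing = sp_iso(1),
    tube_tree = list(tube_segment(c(50, 50, 5), c(50, 50, 115), 40)),
    n_nuclei = 0, nucleus_radius = 3,
    knot_specs = list(list(centre = c(50, 25, 60), n_members = 15,
                           gain = 2, axes = c(20, 10, 5)))
  )
  # sample-covariance oracle: at n = 15 single draws scatter by tens of
  # percent, so compare the median recovered axes over seeds
  axes_hat <- sapply(1:9, function(s) {
    pl <- plant_nuclei(villus, spec, seed = s)
    mem <- pl$centres[pl$knot_membership == 1, ]
    2 * sqrt(eigen(cov(mem), symmetric = TRUE)$values)
  })
  med <- apply(axes_hat, 1, median)
  expect_equal(med / med[1], c(20, 10, 5) / 20, tolerance = 0.25)
  expect_equal(med, c(20, 10, 5), tolerance = 0.25)
})

test_that("rendering obeys the noiseless limit, depth decay and knot gain", {
  shape <- c(80L, 40L, 40L)
  tube <- list(tube_segment(c(5, 20, 20), c(115, 20, 20), 14))
  spec0 <- phantom_spec(shape, sp_iso(1.5), tube, n_nuclei = 20,
                        nucleus_radius = 3, noise_sigma = 0, poisson = FALSE,
                        attenuation_length = 1e12)
  villus <- rasterize_tube_tree(tube, shape, sp_iso(1.5))
  empty <- binary_mask(array(FALSE, shape), sp_iso(1.5))
  pl <- plant_nuclei(villus, spec0, seed = 3)
  st0 <- render_intensity(villus, pl$labels, empty, spec = spec0, seed = 3)
  v <- get_channel(st0, "villi")
  expect_setequal(unique(as.vector(v)), c(0, spec0$base_intensity[["villi"]]))
  expect_true(all(v[villus$data] == spec0$base_intensity[["villi"]]))

  # exponential decay: attenuation length 100 um along a 1.5 um-step axis
  spec_att <- phantom_spec(shape, sp_iso(1.5), tube, n_nuclei = 0,
                           nucleus_radius = 3, noise_sigma = 0,
                           attenuation_length = 100)
  st_att <- render_intensity(villus, label_map(array(0L, shape), sp_iso(1.5)),
                             empty, spec = spec_att, seed = 1)
  va <- get_channel(st_att, "villi")
  surf <- mean(va[5, , ][villus$data[5, , ]])
  deep_z <- which.min(abs((0:(shape[1] - 1)) * 1.5 - (4 * 1.5 + 100))) # 100 um deeper
  deep <- mean(va[deep_z, , ][villus$data[deep_z, , ]])
  expect_equal(deep / surf, exp(-1), tolerance = 0.05)

  # knot gain doubles knot-member intensity at equal depth, noise on
  spec_k <- phantom_spec(
    shape, sp_iso(1.5), tube, n_nuclei = 30, nucleus_radius = 3,
    knot_specs = list(list(centre = c(60, 20, 20), n_members = 12,
                           gain = 2, axes = c(12, 9, 7))),
    noise_sigma = 5, poisson = TRUE, attenuation_length = 1e12
  )
  plk <- plant_nuclei(villus, spec_k, seed = 9)
  kl <- which(plk$knot_membership > 0)
  names(kl) <- as.character(plk$knot_membership[kl])
  stk <- render_intensity(villus, plk$labels, empty, knot_labels = kl,
                          spec = spec_k, seed = 9)
  nu <- get_channel(stk, "nuclei")
  knot_vox <- plk$labels$data %in% kl
  norm_vox <- plk$labels$data > 0 & !knot_vox
  expect_equal(mean(nu[knot_vox]) / mean(nu[norm_vox]), 2, tolerance = 0.1)
})

test_that("the composed phantom is consistent and bit-reproducible", {
  ph <- demo_phantom(42L)
  expect_equal(dim(ph$stack$data)[1], 3)
  expect_equal(ph$stack$channel_names, c("villi", "nuclei", "vessels"))
  # truth masks match the rasterized geometry exactly
  direct <- rasterize_tube_tree(demo_phantom_spec()$tube_tree,
                                demo_phantom_spec()$shape,
                                demo_phantom_spec()$spacing)
  expect_identical(ph$truth$villous_mask$data, direct$data)
  # nesting invariant
  expect_true(all(!ph$truth$vessel_mask$data | ph$truth$villous_mask$data))
  expect_equal(ph$truth$n_junctions, 1L)
  # every knot member centre lies inside the villous mask
  vi <- villomorph:::um_to_voxel(
    ph$truth$nucleus_centres[ph$truth$knot_membership > 0, ],
    ph$truth$villous_mask$spacing
  )
  expect_true(all(ph$truth$villous_mask$data[vi]))
  # full-composition determinism
  ph2 <- generate_phantom(demo_phantom_spec(), 42L)
  expect_identical(ph$stack$data, ph2$stack$data)
  expect_identical(ph$truth$nuclei_labels$data, ph2$truth$nuclei_labels$data)
})
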