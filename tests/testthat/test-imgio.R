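test_that("voxel spacing validates and converts", {
  s <- voxel_spacing(1.5, 0.7, 0.7)
  expect_s3_class(s, "voxel_spacing")
  expect_equal(voxel_volume(s), 1.5 * 0.7 * 0.7)
  expect_error(voxel_spacing(0, 1, 1), "positive")
  expect_error(voxel_spacing(1, -2, 1), "positive")
})

test_that("TIFF stack round trip preserves voxels and spacing", {
  set.seed(11)
  data <- array(sample(0:255, 2 * 6 * 10 * 12, replace = TRUE),
                dim = c(2, 6, 10, 12))
  st <- image_stack(data, voxel_spacing(1.5, 0.7, 0.7),
                    channel_names = c("villi", "nuclei"))
  p <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, p)
  rt <- read_stack(p)
  expect_equal(rt$data, st$data)
  expect_equal(unclass(rt$spacing), unclass(st$spacing), tolerance = 1e-6)
  expect_equal(rt$channel_names, c("villi", "nuclei"))
})

test_that("a plain 3-D TIFF is promoted to one channel with the override spacing", {
  arr <- array(sample(0:255, 5 * 8 * 9, replace = TRUE), dim = c(5, 8, 9))
  p <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(seq_len(5), function(z) arr[z, , ] / 255)
  tiff::writeTIFF(pages, p, bits.per.sample = 8, compression = "none")
  st <- read_stack(p, spacing_override = voxel_spacing(1.5, 0.7, 0.7))
  expect_equal(dim(st$data), c(1L, 5L, 8L, 9L))
  expect_equal(st$data[1, , , ], arr)
  expect_equal(unname(unclass(st$spacing)), c(1.5, 0.7, 0.7))
})

test_that("missing spacing is an error, never a silent default", {
  arr <- matrix(runif(20), 4, 5)
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(arr), p, bits.per.sample = 8, compression = "none")
  expect_error(read_stack(p), "spacing")
})

test_that("NRRD mask round trip is exact, including header spacings", {
  set.seed(7)
  m <- binary_mask(array(runif(10 * 10 * 10) > 0.6, dim = c(10, 10, 10)),
                   voxel_spacing(1.5, 0.7, 0.7))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_mask_nrrd(m, p)
  hdr <- readLines(p, n = 8, warn = FALSE)
  expect_true(any(grepl("spacings: 0.7 0.7 1.5", hdr)))
  rt <- read_mask_nrrd(p)
  expect_identical(rt$data, m$data)
  expect_equal(unclass(rt$spacing), unclass(m$spacing), tolerance = 1e-6)
})

test_that("an all-false mask writes a valid NRRD with zero foreground", {
  m <- binary_mask(array(FALSE, dim = c(6, 5, 4)), voxel_spacing(1, 1, 1))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_mask_nrrd(m, p)
  rt <- read_mask_nrrd(p)
  expect_equal(sum(rt$data), 0)
  expect_equal(dim(rt$data), c(6L, 5L, 4L))
})

test_that("gzip-encoded NRRD is readable", {
  m <- binary_mask(array(runif(5 * 6 * 7) > 0.5, dim = c(5, 6, 7)),
                   voxel_spacing(2, 1, 1))
  p <- withr::local_tempfile(fileext = ".nrrd")
  payload <- memCompress(as.raw(as.integer(aperm(m$data, c(3, 2, 1)))), "gzip")
  con <- file(p, "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3",
               "sizes: 7 6 5", "spacings: 1 1 2",
               "encoding: gzip", ""), con, sep = "\n")
  writeBin(payload, con)
  close(con)
  rt <- read_mask_nrrd(p)
  expect_identical(rt$data, m$data)
})

test_that("label maps round trip through NRRD as integers", {
  lab <- array(0L, dim = c(6, 6, 6))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[5, 5, 5] <- 7L
  lm <- label_map(lab, voxel_spacing(1, 1, 1))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_label_nrrd(lm, p)
  rt <- read_label_map(p)
  expect_identical(rt$data, lm$data)
})

test_that("reports write with the canonical metric schema and round trip", {
  r <- tibble::tibble(
    image_id = "img1", group = "control",
    villous_volume_um3 = 1e5, surface_area_um2 = 1.3e4,
    sa_vol_per_um = 0.13, nuclear_density_per_mm3 = 1.7e6,
    knot_fraction_pct = 3.2, vascular_fraction_pct = 8.5,
    branchpoint_density_per_um = 0.019, mean_tortuosity = 1.01
  )
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_report(r, pc, "csv")
  write_report(r, pj, "json")
  rc <- read_report(pc, "csv")
  rj <- read_report(pj, "json")
  metric_cols <- c(
    "villous_volume_um3", "surface_area_um2", "sa_vol_per_um",
    "nuclear_density_per_mm3", "knot_fraction_pct", "vascular_fraction_pct",
    "branchpoint_density_per_um", "mean_tortuosity"
  )
  expect_true(all(metric_cols %in% names(rc)))
  expect_equal(nrow(rc), 1)
  for (col in metric_cols) {
    expect_equal(rj[[col]], r[[col]], tolerance = 1e-12)
    expect_equal(rc[[col]], r[[col]], tolerance = 1e-12)
  }
  # empty report: header-only CSV
  pe <- withr::local_tempfile(fileext = ".csv")
  write_report(r[0, ], pe, "csv")
  expect_length(readLines(pe, warn = FALSE), 1)
})
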