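# shared fixtures, built in code and memoized for the test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

sp_iso <- function(d = 1) voxel_spacing(d, d, d)

# voxelized ball of radius r (um) centred mid-grid
make_sphere_mask <- function(n, d, r) {
  ax <- (seq_len(n) - 1) * d
  c0 <- mean(range(ax))
  g <- expand.grid(z = ax, y = ax, x = ax, KEEP.OUT.ATTRS = FALSE)
  m <- array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2, dim = rep(n, 3))
  binary_mask(m, sp_iso(d))
}

# x-spanning cylinder of radius r in a (nyz, nyz, nx) grid, spacing 1
make_spanning_cylinder <- function(r = 10, nyz = 32, nx = 200) {
  c0 <- (nyz - 1) / 2
  ax <- seq_len(nyz) - 1
  g <- expand.grid(z = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  disk <- (g$z - c0)^2 + (g$y - c0)^2 <= r^2
  binary_mask(array(rep(disk, nx), dim = c(nyz, nyz, nx)), sp_iso(1))
}

demo_phantom <- function(seed) {
  memo(paste0("demo_", seed), generate_phantom(demo_phantom_spec(), seed))
}

demo_quantified <- function(seed) {
  memo(paste0("quant_", seed), {
    ph <- demo_phantom(seed)
    den <- denoise_median(ph$stack, 1)
    nuc <- segment_nuclei_instances(ph$stack, "nuclei")
    rec <- extract_nucleus_records(nuc, ph$stack, "nuclei")
    list(ph = ph, den = den, nuc = nuc, rec = rec)
  })
}

straight_tube_graph <- function() {
  memo("straight_graph", {
    m <- rasterize_tube_tree(
      list(tube_segment(c(16, 16, 5), c(16, 16, 105), 5)),
      c(32, 32, 111), sp_iso(1)
    )
    build_network(skeletonize(m))
  })
}

y_tube_graph <- function() {
  memo("y_graph", {
    m <- rasterize_tube_tree(
      list(tube_y(c(20, 20, 60),
                  rbind(c(20, 20, 5), c(20, 45, 110), c(20, 5, 100)), 5)),
      c(40, 52, 116), sp_iso(1)
    )
    build_network(skeletonize(m))
  })
}

dice_overlap <- function(a, b) {
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}

# nearest-centroid matching of detected vs planted nuclei
match_detections <- function(detected, truth, radius) {
  if (nrow(detected) == 0 || nrow(truth) == 0) {
    return(list(precision = 0, recall = 0, det_class = integer(0)))
  }
  D <- as.matrix(stats::dist(rbind(detected, truth)))
  D <- D[seq_len(nrow(detected)), nrow(detected) + seq_len(nrow(truth)),
         drop = FALSE]
  list(
    precision = mean(apply(D, 1, min) <= radius),
    recall = mean(apply(D, 2, min) <= radius),
    nearest_truth = apply(D, 1, which.min),
    nearest_dist = apply(D, 1, min),
    truth_matched = apply(D, 2, min) <= radius
  )
}
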