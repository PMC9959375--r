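#' Tube primitives for phantom construction
#'
#' Centreline primitives with a tube radius, used to build synthetic villous
#' trees and nested vessel networks. All coordinates are physical (z, y, x)
#' positions in um. `tube_segment` is a flat-capped cylinder, `tube_arc` a
#' circular-arc tube in the plane spanned by the orthonormal vectors `u`
#' and `v`, `tube_helix` a helical tube sampled as a dense polyline, and
#' `tube_y` a symmetric junction of three segments meeting at one point.
#'
#' @param p0,p1 segment end points, `c(z, y, x)` um.
#' @param radius tube radius, um.
#' @name tube_primitives
NULL

#' @rdname tube_primitives
#' @export
tube_segment <- function(p0, p1, radius) {
  stopifnot(length(p0) == 3, length(p1) == 3, radius > 0)
  structure(list(type = "segment", p0 = as.numeric(p0), p1 = as.numeric(p1),
                 radius = radius), class = "tube_primitive")
}

#' @rdname tube_primitives
#' @param center arc circle centre `c(z, y, x)` um.
#' @param u,v orthonormal in-plane direction vectors.
#' @param arc_radius radius of the centreline circle, um.
#' @param theta angular range `c(t0, t1)` in radians (arc from
#'   `center + arc_radius * (cos(t) u + sin(t) v)`).
#' @export
tube_arc <- function(center, u, v, arc_radius, theta = c(0, pi), radius = 3) {
  u <- u / sqrt(sum(u^2))
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  stopifnot(arc_radius > 0, radius > 0, theta[2] > theta[1])
  structure(list(type = "arc", center = as.numeric(center), u = u, v = v,
                 arc_radius = arc_radius, theta = theta, radius = radius),
            class = "tube_primitive")
}

#' @rdname tube_primitives
#' @param axis_point a point on the helix axis, `c(z, y, x)` um.
#' @param axis unit axis direction.
#' @param helix_radius radius of the helix, um.
#' @param pitch axial advance per turn, um.
#' @param turns number of turns.
#' @export
tube_helix <- function(axis_point, axis, helix_radius, pitch, turns, radius = 3) {
  axis <- axis / sqrt(sum(axis^2))
  structure(list(type = "helix", axis_point = as.numeric(axis_point),
                 axis = axis, helix_radius = helix_radius, pitch = pitch,
                 turns = turns, radius = radius), class = "tube_primitive")
}

#' @rdname tube_primitives
#' @param junction junction point `c(z, y, x)` um.
#' @param tips 3 x 3 matrix of branch tip positions (rows, `c(z, y, x)` um).
#' @export
tube_y <- function(junction, tips, radius) {
  stopifnot(is.matrix(tips), nrow(tips) == 3, ncol(tips) == 3, radius > 0)
  structure(list(type = "yjunction", junction = as.numeric(junction),
                 tips = tips, radius = radius), class = "tube_primitive")
}

# expand composite primitives into simple ones
expand_primitive <- function(p) {
  switch(p$type,
    yjunction = lapply(seq_len(3), function(i) {
      tube_segment(p$junction, p$tips[i, ], p$radius)
    }),
    list(p)
  )
}

# densely sampled centreline polyline of one primitive (matrix of (z,y,x) um)
primitive_polyline <- function(p, step = 0.5) {
  switch(p$type,
    segment = {
      L <- sqrt(sum((p$p1 - p$p0)^2))
      n <- max(2, ceiling(L / step) + 1)
      t <- seq(0, 1, length.out = n)
      outer(1 - t, p$p0) + outer(t, p$p1)
    },
    arc = {
      arclen <- p$arc_radius * diff(p$theta)
      n <- max(2, ceiling(arclen / step) + 1)
      th <- seq(p$theta[1], p$theta[2], length.out = n)
      matrix(rep(p$center, each = n), ncol = 3) +
        p$arc_radius * (outer(cos(th), p$u) + outer(sin(th), p$v))
    },
    helix = {
      total_angle <- 2 * pi * p$turns
      arclen <- p$turns * sqrt((2 * pi * p$helix_radius)^2 + p$pitch^2)
      n <- max(2, ceiling(arclen / step) + 1)
      th <- seq(0, total_angle, length.out = n)
      a <- p$axis
      ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * a) * a
      u <- u / sqrt(sum(u^2))
      v <- c(
        a[2] * u[3] - a[3] * u[2],
        a[3] * u[1] - a[1] * u[3],
        a[1] * u[2] - a[2] * u[1]
      )
      matrix(rep(p$axis_point, each = n), ncol = 3) +
        outer(th / (2 * pi) * p$pitch, a) +
        p$helix_radius * (outer(cos(th), u) + outer(sin(th), v))
    },
    abort(sprintf("unknown primitive type '%s'", p$type))
  )
}

# physical axis coordinate vectors of a grid
axis_um <- function(shape, spacing) {
  sp <- unclass(as_voxel_spacing(spacing))
  list(
    z = (seq_len(shape[1]) - 1) * sp[["dz"]],
    y = (seq_len(shape[2]) - 1) * sp[["dy"]],
    x = (seq_len(shape[3]) - 1) * sp[["dx"]]
  )
}

#' Rasterize a tree of tube primitives into a binary mask
#'
#' A voxel is foreground iff its centre lies within the tube radius of any
#' primitive centreline, with distances computed in physical um (so the
#' result is correct under anisotropic spacing). Segments are flat-capped
#' cylinders; arcs are angularly clamped; helices are rasterized from a
#' dense polyline.
#'
#' @param primitives list of [tube_primitives].
#' @param shape integer `(nz, ny, nx)` voxel counts.
#' @param spacing a [voxel_spacing()].
#' @param check_bounds error if a primitive leaves the grid (default TRUE).
#' @return A [binary_mask()].
#' @export
rasterize_tube_tree <- function(primitives, shape, spacing,
                                check_bounds = TRUE) {
  spacing <- as_voxel_spacing(spacing)
  shape <- as.integer(shape)
  mask <- array(FALSE, dim = shape)
  prims <- unlist(lapply(primitives, expand_primitive), recursive = FALSE)
  ax <- axis_um(shape, spacing)
  extent <- c(max(ax$z), max(ax$y), max(ax$x))
  for (p in prims) {
    pl <- primitive_polyline(p, step = min(unclass(spacing)) / 2)
    lo <- apply(pl, 2, min) - p$radius
    hi <- apply(pl, 2, max) + p$radius
    if (check_bounds &&
        (any(apply(pl, 2, min) < -1e-9) || any(apply(pl, 2, max) > extent + 1e-9))) {
      abort("primitive centreline lies outside the grid bounds")
    }
    iz <- which(ax$z >= lo[1] & ax$z <= hi[1])
    iy <- which(ax$y >= lo[2] & ax$y <= hi[2])
    ix <- which(ax$x >= lo[3] & ax$x <= hi[3])
    if (!length(iz) || !length(iy) || !length(ix)) next
    g <- expand.grid(z = ax$z[iz], y = ax$y[iy], x = ax$x[ix],
                     KEEP.OUT.ATTRS = FALSE)
    inside <- primitive_inside(p, g$z, g$y, g$x)
    sub <- array(inside, dim = c(length(iz), length(iy), length(ix)))
    mask[iz, iy, ix] <- mask[iz, iy, ix] | sub
  }
  binary_mask(mask, spacing)
}

# vectorized membership test for one simple primitive
primitive_inside <- function(p, z, y, x) {
  r2 <- p$radius^2
  if (p$type == "segment") {
    w <- p$p1 - p$p0
    L <- sqrt(sum(w^2))
    u <- w / L
    tz <- z - p$p0[1]; ty <- y - p$p0[2]; tx <- x - p$p0[3]
    t <- tz * u[1] + ty * u[2] + tx * u[3]
    perp2 <- (tz - t * u[1])^2 + (ty - t * u[2])^2 + (tx - t * u[3])^2
    t >= 0 & t <= L & perp2 <= r2
  } else if (p$type == "arc") {
    rel_z <- z - p$center[1]; rel_y <- y - p$center[2]; rel_x <- x - p$center[3]
    nrm <- c(
      p$u[2] * p$v[3] - p$u[3] * p$v[2],
      p$u[3] * p$v[1] - p$u[1] * p$v[3],
      p$u[1] * p$v[2] - p$u[2] * p$v[1]
    )
    a <- rel_z * p$u[1] + rel_y * p$u[2] + rel_x * p$u[3]
    b <- rel_z * p$v[1] + rel_y * p$v[2] + rel_x * p$v[3]
    h <- rel_z * nrm[1] + rel_y * nrm[2] + rel_x * nrm[3]
    rho <- sqrt(a^2 + b^2)
    th <- atan2(b, a)
    th <- ifelse(th < p$theta[1], th + 2 * pi, th)
    in_range <- th >= p$theta[1] & th <= p$theta[2]
    in_range & ((rho - p$arc_radius)^2 + h^2 <= r2)
  } else if (p$type == "helix") {
    pl <- primitive_polyline(p, step = p$radius / 4)
    inside <- rep(FALSE, length(z))
    # distance to polyline via chained capsule segments
    for (i in seq_len(nrow(pl) - 1)) {
      p0 <- pl[i, ]; p1 <- pl[i + 1, ]
      w <- p1 - p0
      L2 <- sum(w^2)
      tz <- z - p0[1]; ty <- y - p0[2]; tx <- x - p0[3]
      t <- pmin(pmax((tz * w[1] + ty * w[2] + tx * w[3]) / L2, 0), 1)
      d2 <- (tz - t * w[1])^2 + (ty - t * w[2])^2 + (tx - t * w[3])^2
      inside <- inside | d2 <= r2
    }
    inside
  } else {
    abort(sprintf("unknown primitive type '%s'", p$type))
  }
}

#' Specification of a synthetic villous phantom
#'
#' Collects everything needed to generate a reproducible synthetic stack:
#' grid geometry, villous tube tree, nested vessel tree, nuclear shell
#' parameters, planted knot clusters, noise and depth attenuation.
#'
#' @param shape `(nz, ny, nx)` voxel counts.
#' @param spacing a [voxel_spacing()].
#' @param tube_tree list of [tube_primitives] forming the villous mask.
#' @param vessel_tree list of [tube_primitives] forming the vessel mask;
#'   vessel radii must be smaller than the enclosing villous radii.
#' @param n_nuclei number of dispersed (non-knot) nuclei.
#' @param nucleus_radius nucleus sphere radius, um.
#' @param knot_specs list of knot descriptions, each
#'   `list(centre = c(z,y,x), n_members =, gain =, axes = c(L1,L2,L3))`
#'   where `axes` are the planted principal-axis lengths (um); member
#'   centres are drawn from the anisotropic Gaussian with standard
#'   deviations `axes / 2` along random (seeded) orthonormal directions.
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   units); 0 disables.
#' @param poisson logical, Poisson-resample intensities before the Gaussian
#'   noise.
#' @param attenuation_length exponential depth-attenuation length, um
#'   (`Inf` disables).
#' @param base_intensity named intensities for the noiseless foreground of
#'   the three channels; chosen so the brightest structures (knot nuclei at
#'   their gain) stay inside the bit-depth range, as in a well-set
#'   acquisition (no detector clipping).
#' @param bit_depth 8 or 16.
#' @param n_junctions planted number of vessel junctions (for composite
#'   trees built from segments; `tube_y` primitives are counted
#'   automatically when `NULL`).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape, spacing, tube_tree, vessel_tree = list(),
                         n_nuclei = 0, nucleus_radius = 3,
                         knot_specs = list(), noise_sigma = 0,
                         poisson = FALSE, attenuation_length = Inf,
                         base_intensity = c(villi = 120, nuclei = 110,
                                            vessels = 160),
                         bit_depth = 8L, n_junctions = NULL) {
  if (attenuation_length <= 0) abort("attenuation_length must be positive")
  for (ks in knot_specs) {
    if (ks$n_members < 2) abort("knot member count must be >= 2")
  }
  vr <- vapply(unlist(lapply(vessel_tree, expand_primitive), recursive = FALSE),
               function(p) p$radius, numeric(1))
  tr <- vapply(unlist(lapply(tube_tree, expand_primitive), recursive = FALSE),
               function(p) p$radius, numeric(1))
  if (length(vr) && length(tr) && max(vr) >= max(tr)) {
    abort("vessel radii must be strictly smaller than enclosing villous radii")
  }
  if (is.null(n_junctions)) {
    n_junctions <- sum(vapply(vessel_tree, function(p) p$type == "yjunction",
                              logical(1)))
  }
  structure(
    list(
      shape = as.integer(shape), spacing = as_voxel_spacing(spacing),
      tube_tree = tube_tree, vessel_tree = vessel_tree,
      n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
      knot_specs = knot_specs, noise_sigma = noise_sigma, poisson = poisson,
      attenuation_length = attenuation_length,
      base_intensity = base_intensity, bit_depth = as.integer(bit_depth),
      n_junctions = as.integer(n_junctions)
    ),
    class = "phantom_spec"
  )
}

#' Default demonstration phantom
#'
#' A field emulating a cropped multiphoton acquisition at the typical
#' anisotropic spacing (1.5 x 0.7 x 0.7 um): a branching villous tube with a
#' nested Y-branched vessel, a shell of ~150 trophoblast-like nuclei, and two
#' planted bright knot clusters (one round, one elongated), imaged with
#' Poisson + Gaussian noise and exponential depth attenuation.
#'
#' @param shape grid size, default `c(100, 128, 128)` voxels (z, y, x).
#' @param noise_sigma Gaussian noise sd, default 8 (8-bit units).
#' @param n_nuclei dispersed nuclei, default 150.
#' @return A [phantom_spec()].
#' @export
demo_phantom_spec <- function(shape = c(100L, 128L, 128L), noise_sigma = 8,
                              n_nuclei = 150) {
  spacing <- voxel_spacing(1.5, 0.7, 0.7)
  ext <- (shape - 1) * unclass(spacing)[c("dz", "dy", "dx")] # (z,y,x) um
  zc <- ext[1] / 2
  # main villous trunk along x with a side branch
  villi <- list(
    tube_segment(c(zc, ext[2] * 0.45, 4), c(zc, ext[2] * 0.45, ext[3] - 4), 18),
    tube_segment(c(zc, ext[2] * 0.45, ext[3] * 0.45),
                 c(zc, ext[2] * 0.88, ext[3] * 0.78), 13)
  )
  # nested Y-branched vessel inside the trunk
  jx <- ext[3] * 0.5
  vessels <- list(
    tube_y(
      junction = c(zc, ext[2] * 0.45, jx),
      tips = rbind(
        c(zc, ext[2] * 0.45, 6),
        c(zc + 12, ext[2] * 0.52, ext[3] - 6),
        c(zc - 12, ext[2] * 0.36, ext[3] - 10)
      ),
      radius = 5
    )
  )
  knots <- list(
    list(centre = c(zc + 6, ext[2] * 0.45 + 14, ext[3] * 0.3),
         n_members = 15, gain = 2, axes = c(10, 8, 7)),
    list(centre = c(zc - 6, ext[2] * 0.45 - 14, ext[3] * 0.7),
         n_members = 15, gain = 2, axes = c(16, 8, 5))
  )
  phantom_spec(
    shape = shape, spacing = spacing, tube_tree = villi,
    vessel_tree = vessels, n_nuclei = n_nuclei, nucleus_radius = 3,
    knot_specs = knots, noise_sigma = noise_sigma, poisson = TRUE,
    attenuation_length = 150, n_junctions = 1L
  )
}

#' Random branching tube tree with a known junction count
#'
#' Builds a randomized binary tree of tube segments growing along +x with
#' jittered branch angles, for validating junction detection: the number
#' of planted junctions is exact by construction and branch angles/lengths
#' are kept large enough that distinct branches do not merge.
#'
#' @param n_junctions number of bifurcations to plant (>= 0).
#' @param seed integer seed.
#' @param radius tube radius, um.
#' @param extent physical size `c(z, y, x)` of the target box, um.
#' @param seg_length segment length, um.
#' @return list with `primitives` (for [rasterize_tube_tree()]),
#'   `n_junctions`, and the `tips` matrix.
#' @export
tube_random_tree <- function(n_junctions, seed, radius = 4,
                             extent = c(70, 170, 170), seg_length = 30) {
  withr_seed(seed, {
    z0 <- extent[1] / 2
    y0 <- extent[2] / 2
    prims <- list()
    # active tips: position, azimuth (y-x plane), z-tilt
    tips <- list(list(pos = c(z0, y0, 6), phi = 0, tilt = 0))
    grow <- function(tip, dphi, dtilt) {
      phi <- tip$phi + dphi
      tilt <- max(min(tip$tilt + dtilt, 0.35), -0.35)
      d <- c(sin(tilt), cos(tilt) * sin(phi), cos(tilt) * cos(phi))
      p1 <- tip$pos + seg_length * d
      if (any(p1 < radius + 2) || any(p1 > extent - radius - 2)) return(NULL)
      list(pos = p1, phi = phi, tilt = tilt, seg = tube_segment(tip$pos, p1, radius))
    }
    # reject candidate segments that pass within clearance of an existing
    # segment they do not share an endpoint with (a collision would create
    # an unplanned junction in the rasterized mask)
    seg_points <- function(seg, step = 3) {
      L <- sqrt(sum((seg$p1 - seg$p0)^2))
      t <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
      outer(1 - t, seg$p0) + outer(t, seg$p1)
    }
    clearance <- 2 * radius + 3
    collides <- function(seg) {
      if (!length(prims)) return(FALSE)
      pts <- seg_points(seg)
      for (other in prims) {
        shared <- min(
          sqrt(sum((seg$p0 - other$p0)^2)), sqrt(sum((seg$p0 - other$p1)^2)),
          sqrt(sum((seg$p1 - other$p0)^2)), sqrt(sum((seg$p1 - other$p1)^2))
        ) < 1e-6
        if (shared) next
        opts <- seg_points(other)
        dmin <- sqrt(min(outer(rowSums(pts^2), rep(1, nrow(opts))) +
                           outer(rep(1, nrow(pts)), rowSums(opts^2)) -
                           2 * pts %*% t(opts)))
        if (dmin < clearance) return(TRUE)
      }
      FALSE
    }
    # root segment
    g <- grow(tips[[1]], 0, 0)
    prims[[1]] <- g$seg
    tips <- list(g[c("pos", "phi", "tilt")])
    done <- 0L
    guard <- 0L
    while (done < n_junctions) {
      guard <- guard + 1L
      if (guard > 1000L) abort("could not place the requested junctions without collisions")
      i <- sample.int(length(tips), 1)
      tip <- tips[[i]]
      placed <- FALSE
      for (try in 1:10) {
        ang <- 0.5 + runif(2) * 0.35 # 29-49 degrees
        g1 <- grow(tip, ang[1], runif(1, -0.15, 0.15))
        g2 <- grow(tip, -ang[2], runif(1, -0.15, 0.15))
        if (is.null(g1) || is.null(g2)) next
        sep <- sqrt(sum((g1$pos - g2$pos)^2))
        if (sep < clearance) next
        if (collides(g1$seg) || collides(g2$seg)) next
        placed <- TRUE
        break
      }
      if (!placed) next
      prims[[length(prims) + 1L]] <- g1$seg
      prims[[length(prims) + 1L]] <- g2$seg
      tips[[i]] <- g1[c("pos", "phi", "tilt")]
      tips[[length(tips) + 1L]] <- g2[c("pos", "phi", "tilt")]
      done <- done + 1L
    }
    list(primitives = prims, n_junctions = n_junctions,
         tips = do.call(rbind, lapply(tips, `[[`, "pos")))
  })
}

#' Plant nuclei (and knot clusters) in a villous mask
#'
#' Dispersed nuclei are placed by rejection sampling in a surface shell
#' (within `2 * nucleus_radius` of the villous boundary) with a minimum
#' centre separation of `1.5 * nucleus_radius`; knot members are drawn from
#' an anisotropic Gaussian around each knot centre (the planted covariance
#' axes are recorded in the returned truth). Spheres are stamped into a
#' label map, with voxels in overlaps assigned to the nearest centre so
#' every label stays connected. Deterministic given `seed`.
#'
#' @param villous_mask a non-empty [binary_mask()].
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with `labels` (a [label_map()]), `centres` (n x 3 um),
#'   `knot_membership` (integer per nucleus, 0 = dispersed),
#'   `knot_axes` (list of planted axis systems).
#' @export
plant_nuclei <- function(villous_mask, spec, seed) {
  stopifnot(inherits(villous_mask, "binary_mask"))
  if (!any(villous_mask$data)) abort("villous mask is empty")
  sp <- unclass(villous_mask$spacing)
  r_n <- spec$nucleus_radius
  withr_seed(seed, {
    dist_in <- cpp_edt(villous_mask$data, sp[["dz"]], sp[["dy"]], sp[["dx"]])
    # surface shell: within two radii of the boundary, with centres at
    # least half a radius deep (nuclei are anchored in the tissue; only
    # their outer cap may protrude)
    shell_idx <- which(villous_mask$data & dist_in <= 2 * r_n &
                         dist_in >= 0.5 * r_n)
    if (!length(shell_idx)) abort("villous mask has no surface shell")
    shell_pos <- voxel_to_um(arrayInd(shell_idx, dim(villous_mask$data)),
                             villous_mask$spacing)
    centres <- matrix(numeric(0), ncol = 3)
    min_sep <- 1.5 * r_n
    draws <- 0L
    max_draws <- 100L * max(spec$n_nuclei, 1L)
    while (nrow(centres) < spec$n_nuclei) {
      draws <- draws + 1L
      if (draws > max_draws) {
        abort(sprintf(
          "nucleus placement failed after %d draws; mask too small for %d nuclei",
          max_draws, spec$n_nuclei
        ))
      }
      cand <- shell_pos[sample.int(nrow(shell_pos), 1L), ] +
        (runif(3) - 0.5) * sp[c("dz", "dy", "dx")]
      if (nrow(centres) > 0) {
        d2 <- colSums((t(centres) - cand)^2)
        if (min(d2) < min_sep^2) next
      }
      centres <- rbind(centres, cand)
    }
    membership <- rep(0L, nrow(centres))
    knot_axes <- list()
    for (k in seq_along(spec$knot_specs)) {
      ks <- spec$knot_specs[[k]]
      rot <- random_rotation()
      sds <- sort(ks$axes, decreasing = TRUE) / 2
      sigma <- rot %*% diag(sds^2) %*% t(rot)
      members <- matrix(numeric(0), ncol = 3)
      tries <- 0L
      while (nrow(members) < ks$n_members) {
        tries <- tries + 1L
        if (tries > 100L * ks$n_members) {
          abort("knot member placement failed; knot centre too close to the mask boundary?")
        }
        m <- MASS::mvrnorm(1, mu = ks$centre, Sigma = sigma)
        vi <- um_to_voxel(m, villous_mask$spacing)
        if (any(vi < 1) || any(vi > dim(villous_mask$data))) next
        if (!villous_mask$data[vi[1], vi[2], vi[3]]) next
        # hard-core packing: nuclei are incompressible; touching nuclei
        # have ~2r centre separation, so all nuclei (dispersed, earlier
        # knots, and members of this knot) keep 1.5r (slightly compressed
        # contact) between centres
        placed <- rbind(centres, members)
        if (nrow(placed) > 0 &&
            min(colSums((t(placed) - m)^2)) < (1.5 * r_n)^2) next
        members <- rbind(members, m)
      }
      membership <- c(membership, rep.int(k, ks$n_members))
      centres <- rbind(centres, members)
      knot_axes[[k]] <- list(axes = sort(ks$axes, decreasing = TRUE),
                             rotation = rot, centre = ks$centre)
    }
    labels <- stamp_nuclei(centres, r_n, dim(villous_mask$data),
                           villous_mask$spacing)
    list(
      labels = label_map(labels, villous_mask$spacing),
      centres = unname(as.matrix(centres)),
      knot_membership = membership,
      knot_axes = knot_axes
    )
  })
}

# deterministic seeded evaluation without touching the global RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# uniform random rotation matrix (QR of Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# stamp spheres of radius r at centres; overlap resolved by nearest centre
stamp_nuclei <- function(centres, r, shape, spacing) {
  sp <- unclass(as_voxel_spacing(spacing))
  labels <- array(0L, dim = shape)
  if (nrow(centres) == 0) return(labels)
  best_d2 <- array(Inf, dim = shape)
  ax <- axis_um(shape, spacing)
  for (i in seq_len(nrow(centres))) {
    c_i <- centres[i, ]
    iz <- which(abs(ax$z - c_i[1]) <= r)
    iy <- which(abs(ax$y - c_i[2]) <= r)
    ix <- which(abs(ax$x - c_i[3]) <= r)
    if (!length(iz) || !length(iy) || !length(ix)) next
    g <- expand.grid(z = ax$z[iz], y = ax$y[iy], x = ax$x[ix],
                     KEEP.OUT.ATTRS = FALSE)
    d2 <- (g$z - c_i[1])^2 + (g$y - c_i[2])^2 + (g$x - c_i[3])^2
    sub_d2 <- array(d2, dim = c(length(iz), length(iy), length(ix)))
    cur_d2 <- best_d2[iz, iy, ix]
    cur_lab <- labels[iz, iy, ix]
    take <- sub_d2 <= r^2 & sub_d2 < cur_d2
    cur_lab[take] <- i
    cur_d2[take] <- sub_d2[take]
    labels[iz, iy, ix] <- cur_lab
    best_d2[iz, iy, ix] <- cur_d2
  }
  labels
}

#' Render a noisy intensity stack from phantom masks
#'
#' Per channel: foreground base intensity scaled by exponential depth
#' attenuation `exp(-z_um / attenuation_length)`; knot-member nuclei are
#' multiplied by their planted gain; then optional Poisson resampling,
#' additive Gaussian noise, and clipping to the bit depth. Deterministic
#' given `seed`.
#'
#' @param villous_mask,vessel_mask [binary_mask()] objects.
#' @param nuclei_labels a [label_map()].
#' @param knot_labels integer vector of nucleus labels that belong to knots
#'   (these get the gain).
#' @param spec a [phantom_spec()] (noise/attenuation/intensity parameters).
#' @param seed integer seed.
#' @return An [image_stack()] with channels `villi`, `nuclei`, `vessels`.
#' @export
render_intensity <- function(villous_mask, nuclei_labels, vessel_mask,
                             knot_labels = integer(0), spec, seed) {
  check_same_geometry(villous_mask, vessel_mask)
  check_same_geometry(villous_mask, nuclei_labels)
  shape <- dim(villous_mask$data)
  sp <- unclass(villous_mask$spacing)
  gains <- spec$knot_specs
  atten <- exp(-(seq_len(shape[1]) - 1) * sp[["dz"]] / spec$attenuation_length)
  att3 <- array(rep(atten, times = prod(shape[2:3])), dim = shape)
  base <- spec$base_intensity
  maxval <- 2^spec$bit_depth - 1

  nuc_int <- array(0, dim = shape)
  nz <- nuclei_labels$data > 0L
  nuc_int[nz] <- base[["nuclei"]]
  if (length(knot_labels)) {
    # per-label gain; names of knot_labels give the owning knot index
    gain_of <- rep(1, max(max(nuclei_labels$data), 1L))
    knot_idx <- if (is.null(names(knot_labels))) {
      rep(1L, length(knot_labels))
    } else {
      as.integer(names(knot_labels))
    }
    for (i in seq_along(knot_labels)) {
      gain_of[knot_labels[i]] <- spec$knot_specs[[knot_idx[i]]]$gain
    }
    in_knot <- nz & gain_of[pmax(nuclei_labels$data, 1L)] > 1
    nuc_int[in_knot] <- base[["nuclei"]] * gain_of[nuclei_labels$data[in_knot]]
  }

  channels <- list(
    villi = base[["villi"]] * villous_mask$data,
    nuclei = nuc_int,
    vessels = base[["vessels"]] * vessel_mask$data
  )
  withr_seed(seed, {
    data <- array(0, dim = c(3, shape))
    for (i in seq_along(channels)) {
      v <- channels[[i]] * att3
      if (spec$poisson) {
        v[] <- rpois(length(v), lambda = as.vector(v))
      }
      if (spec$noise_sigma > 0) {
        v <- v + rnorm(length(v), sd = spec$noise_sigma)
      }
      v <- pmin(pmax(round(v), 0), maxval)
      data[i, , , ] <- v
    }
    image_stack(data, villous_mask$spacing,
                channel_names = names(channels), bit_depth = spec$bit_depth)
  })
}

#' Generate a complete phantom stack with planted ground truth
#'
#' Composes [rasterize_tube_tree()], [plant_nuclei()] and
#' [render_intensity()] into a 3-channel stack (`villi`, `nuclei`,
#' `vessels`) plus a `phantom_truth` list: planted masks, nucleus centres,
#' knot memberships and axes, sampled vessel centrelines and the junction
#' count. Bit-reproducible for a fixed `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with elements `stack` ([image_stack()]) and `truth`.
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  villous <- rasterize_tube_tree(spec$tube_tree, spec$shape, spec$spacing)
  if (length(spec$vessel_tree)) {
    vessel <- rasterize_tube_tree(spec$vessel_tree, spec$shape, spec$spacing)
    # nested vessels never leave the villous support
    vessel$data <- vessel$data & villous$data
  } else {
    vessel <- binary_mask(array(FALSE, spec$shape), spec$spacing)
  }
  planted <- plant_nuclei(villous, spec, seed)
  knot_labels <- which(planted$knot_membership > 0)
  names(knot_labels) <- as.character(
    planted$knot_membership[planted$knot_membership > 0]
  )
  stack <- render_intensity(villous, planted$labels, vessel,
                            knot_labels = knot_labels, spec = spec,
                            seed = seed + 1L)
  centrelines <- lapply(
    unlist(lapply(spec$vessel_tree, expand_primitive), recursive = FALSE),
    primitive_polyline
  )
  truth <- list(
    villous_mask = villous,
    vessel_mask = vessel,
    nuclei_labels = planted$labels,
    nucleus_centres = planted$centres,
    knot_membership = planted$knot_membership,
    knot_axes = planted$knot_axes,
    centrelines = centrelines,
    n_junctions = spec$n_junctions,
    nucleus_radius = spec$nucleus_radius
  )
  list(stack = stack, truth = truth)
}
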