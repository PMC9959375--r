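#' Density-based clustering of 3-D points (DBSCAN)
#'
#' The clustering core of knot detection. A point is a core point iff it
#' has at least `min_pts` neighbours within `eps` (inclusive Euclidean
#' distance, the point itself counted); clusters are the connected
#' components of core points under eps-adjacency, plus their border points.
#' Border points reachable from two clusters are assigned to the cluster of
#' their lowest-index core neighbour, which makes the labelling
#' deterministic across runs and platforms. Cluster ids are assigned in
#' order of each cluster's first core point; noise is 0.
#'
#' Neighbour search uses an eps-sized grid hash, so typical point clouds
#' cluster in near-linear time.
#'
#' @param points n x 3 matrix of physical positions (um), or a data frame
#'   with columns `cz`, `cy`, `cx`.
#' @param eps neighbourhood radius, um.
#' @param min_pts minimum neighbourhood size for a core point.
#' @return integer vector of cluster ids (0 = noise), one per point.
#' @export
dbscan_cluster <- function(points, eps, min_pts) {
  if (eps <= 0) abort("eps must be positive")
  if (min_pts < 1) abort("min_pts must be >= 1")
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  nbrs <- eps_neighbours(pts, eps)
  is_core <- vapply(nbrs, length, integer(1)) + 1L >= min_pts # self counted
  cl <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || cl[i] != 0L) next
    next_id <- next_id + 1L
    queue <- i
    cl[i] <- next_id
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (is_core[q] && cl[q] == 0L) {
          cl[q] <- next_id
          queue <- c(queue, q)
        }
      }
    }
  }
  # border points: lowest-index core neighbour wins
  for (i in seq_len(n)) {
    if (is_core[i] || cl[i] != 0L) next
    cores <- nbrs[[i]][is_core[nbrs[[i]]]]
    if (length(cores)) cl[i] <- cl[min(cores)]
  }
  cl
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("cz", "cy", "cx") %in% names(points))) {
      points <- as.matrix(points[, c("cz", "cy", "cx")])
    } else {
      points <- as.matrix(points)
    }
  }
  if (length(points) == 0) return(matrix(numeric(0), ncol = 3))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  unname(points)
}

# neighbour lists (indices, self excluded) within eps, via grid hashing
eps_neighbours <- function(pts, eps) {
  n <- nrow(pts)
  cell <- pmax(floor(sweep(pts, 2, apply(pts, 2, min)) / eps), 0) + 1
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  by_cell <- split(seq_len(n), key)
  cell_of <- match(key, names(by_cell))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (k in seq_len(nrow(offs))) {
      ck <- paste(cell[i, 1] + offs[k, 1], cell[i, 2] + offs[k, 2],
                  cell[i, 3] + offs[k, 3])
      hit <- by_cell[[ck]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2 +
        (pts[cand, 3] - pts[i, 3])^2
      cand <- sort(cand[d2 <= eps2])
    }
    nbrs[[i]] <- cand
  }
  nbrs
}

#' Principal-axis shape of a point cloud: axis lengths, EI and FI
#'
#' Eigen-decomposition of the position covariance; axis lengths are
#' `L_i = 2 * sqrt(eigenvalue_i)` sorted descending. The elongation index
#' is `EI = L2 / L1` (intermediate over longest principal axis) and the
#' flatness index `FI = L3 / L2` (shortest over intermediate) — the 3-D
#' shape descriptors used to phenotype syncytial knots (a sphere has
#' EI = FI = 1; a flat plate has small FI; a rod has small EI).
#'
#' @param positions n x 3 matrix of physical voxel positions (um) of all
#'   voxels of the member nuclei; at least 4 non-coplanar points.
#' @return list with `L1`, `L2`, `L3` (um), `EI`, `FI`, and the `axes`
#'   eigenvector matrix (columns, descending).
#' @export
knot_shape <- function(positions) {
  pts <- as_point_matrix(positions)
  if (nrow(pts) < 4) abort("knot shape needs at least 4 positions")
  cv <- cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  vals <- ev$values
  tol <- max(vals) * 1e-9
  rank <- sum(vals > tol)
  if (rank < 3) {
    abort(sprintf(
      "degenerate point set (covariance rank %d < 3: %s); axes undefined",
      rank, if (rank <= 1) "collinear" else "coplanar"
    ))
  }
  L <- 2 * sqrt(vals)
  list(L1 = L[1], L2 = L[2], L3 = L[3], EI = L[2] / L[1], FI = L[3] / L[2],
       axes = ev$vectors)
}

#' Detect syncytial knots as dense clusters of nuclei
#'
#' Reconstructs the knot-mining stage from its stated ingredients: knots in
#' the nuclear channel appear bright and very dense, so nuclei are
#' optionally gated on intensity (`mean_intensity >= intensity_gate *
#' median`), their centroids clustered with [dbscan_cluster()], and
#' clusters with at least `min_members` nuclei become knot records with
#' shape computed by [knot_shape()] on the member nuclei's voxel cloud.
#' Knot volume is the sum of member nucleus volumes. The thresholds are
#' deliberately explicit configuration: defaults are a reconstruction (eps
#' of twice a typical nucleus radius, DBSCAN `min_pts` 4, and the common
#' histopathological convention of about ten aggregated nuclei to call a
#' knot), not published values.
#'
#' @param records nucleus records tibble (see [extract_nucleus_records()]).
#' @param labels the [label_map()] the records came from.
#' @param eps DBSCAN radius, um.
#' @param min_pts DBSCAN core-point threshold.
#' @param min_members minimum nuclei per reported knot.
#' @param intensity_gate optional fraction of the median nucleus intensity;
#'   `NULL` disables gating.
#' @return tibble with one row per knot: `knot_id`, `n_members`,
#'   `volume_um3`, `L1`, `L2`, `L3`, `EI`, `FI`, centroid `cz`, `cy`, `cx`,
#'   and a `member_labels` list column.
#' @export
detect_knots <- function(records, labels, eps = 6, min_pts = 4L,
                         min_members = 10L, intensity_gate = NULL) {
  stopifnot(inherits(labels, "label_map"))
  empty <- tibble(
    knot_id = integer(0), n_members = integer(0), volume_um3 = numeric(0),
    L1 = numeric(0), L2 = numeric(0), L3 = numeric(0),
    EI = numeric(0), FI = numeric(0),
    cz = numeric(0), cy = numeric(0), cx = numeric(0),
    member_labels = list()
  )
  if (nrow(records) == 0) return(empty)
  gated <- records
  if (!is.null(intensity_gate)) {
    if (all(is.na(records$mean_intensity))) {
      inform("no intensities available (external label map without a stack); intensity gate skipped")
    } else {
      med <- median(records$mean_intensity, na.rm = TRUE)
      gated <- dplyr::filter(records,
                             .data$mean_intensity >= intensity_gate * med)
    }
  }
  if (nrow(gated) == 0) return(empty)
  cl <- dbscan_cluster(gated, eps = eps, min_pts = min_pts)
  keep_ids <- sort(unique(cl[cl > 0]))
  out <- list()
  next_knot <- 0L
  for (id in keep_ids) {
    members <- gated$label[cl == id]
    if (length(members) < min_members) next
    next_knot <- next_knot + 1L
    vox_idx <- which(labels$data %in% members)
    pos <- voxel_to_um(arrayInd(vox_idx, dim(labels$data)), labels$spacing)
    shp <- knot_shape(pos)
    out[[next_knot]] <- tibble(
      knot_id = next_knot,
      n_members = length(members),
      volume_um3 = sum(gated$volume_um3[cl == id]),
      L1 = shp$L1, L2 = shp$L2, L3 = shp$L3, EI = shp$EI, FI = shp$FI,
      cz = mean(pos[, 1]), cy = mean(pos[, 2]), cx = mean(pos[, 3]),
      member_labels = list(members)
    )
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Knot volume fraction of the villous volume
#'
#' `100 * sum(knot volumes) / villous volume` — the total volume of
#' aggregated knot nuclei normalised to the villus they sit on.
#'
#' @param knots knot records tibble from [detect_knots()].
#' @param villous_volume villous volume in um^3 (> 0).
#' @return percentage.
#' @export
knot_fraction <- function(knots, villous_volume) {
  if (villous_volume <= 0) abort("villous volume must be positive")
  if (nrow(knots) == 0) return(0)
  100 * sum(knots$volume_um3) / villous_volume
}
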