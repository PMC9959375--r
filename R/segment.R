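#' Denoise a stack with a 3-D median filter
#'
#' Applies a `(2r+1)^3` median per channel with reflective borders, the
#' standard pre-processing step before threshold segmentation of
#' multiphoton stacks. The integer dtype and bit depth are preserved.
#'
#' @param stack an [image_stack()].
#' @param radius neighbourhood radius in voxels (>= 1).
#' @return A denoised [image_stack()].
#' @export
denoise_median <- function(stack, radius = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (radius < 1) abort("median radius must be >= 1")
  out <- stack
  for (ch in seq_len(dim(stack$data)[1])) {
    arr <- get_channel(stack, ch)
    out$data[ch, , , ] <- cpp_median3d(arr, as.integer(radius))
  }
  out
}

# global Otsu threshold on a 3-D array (histogram over all voxels)
otsu_threshold <- function(arr, maxval) {
  v <- as.vector(arr)
  if (max(v) == min(v)) {
    abort("degenerate histogram: channel is constant, Otsu threshold undefined")
  }
  breaks <- seq(0, maxval, length.out = 257L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = 256L)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1L] # upper edge of the argmax bin
}

#' Threshold-segment one channel into a binary mask
#'
#' Global thresholding (Otsu on the intensity histogram, or a fixed value),
#' followed by removal of connected components smaller than a physical
#' volume (26-connectivity) and optional per-slice hole filling.
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param method `"otsu"` or a fixed numeric threshold (mask is
#'   `intensity >= t`).
#' @param min_size_um3 drop components smaller than this volume (um^3).
#' @param fill_holes fill enclosed background per z-slice.
#' @return A [binary_mask()].
#' @export
segment_channel <- function(stack, channel, method = "otsu",
                            min_size_um3 = 0, fill_holes = FALSE) {
  arr <- get_channel(stack, channel)
  maxval <- 2^stack$bit_depth - 1
  thr <- if (identical(method, "otsu")) {
    otsu_threshold(arr, maxval)
  } else if (is.numeric(method)) {
    method
  } else {
    abort("method must be \"otsu\" or a numeric threshold")
  }
  mask <- arr >= thr
  if (min_size_um3 > 0 && any(mask)) {
    lab <- cpp_label26(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * voxel_volume(stack$spacing) >= min_size_um3)
    mask <- array(lab %in% keep, dim = dim(mask))
  }
  if (fill_holes) mask <- fill_holes_slicewise(mask)
  binary_mask(mask, stack$spacing)
}

# fill enclosed background per z-slice (4-connectivity flood from the
# slice border; anything not reached is a hole)
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    mask[z, , ] <- fill_holes_2d(sl)
  }
  mask
}

fill_holes_2d <- function(sl) {
  ny <- nrow(sl); nx <- ncol(sl)
  outside <- matrix(FALSE, ny, nx)
  queue <- integer(0)
  push <- function(i) queue <<- c(queue, i)
  for (y in seq_len(ny)) for (x in c(1L, nx)) {
    if (!sl[y, x]) outside[y, x] <- TRUE
  }
  for (x in seq_len(nx)) for (y in c(1L, ny)) {
    if (!sl[y, x]) outside[y, x] <- TRUE
  }
  # iterative dilation-constrained flood (vectorized; few passes)
  repeat {
    grown <- outside
    grown[-1, ] <- grown[-1, ] | outside[-ny, ]
    grown[-ny, ] <- grown[-ny, ] | outside[-1, ]
    grown[, -1] <- grown[, -1] | outside[, -nx]
    grown[, -nx] <- grown[, -nx] | outside[, -1]
    grown <- grown & !sl
    if (identical(grown, outside)) break
    outside <- grown
  }
  sl | (!outside & !sl)
}

#' Instance-segment nuclei with multi-scale LoG seeding and watershed
#'
#' Classical nucleus instance segmentation for densely packed 3-D nuclei:
#' seeds are local maxima of the scale-normalized Laplacian-of-Gaussian
#' response computed over a range of physical scales (per-axis sigmas are
#' converted through the voxel spacing, so anisotropic stacks are handled
#' correctly), suppressed below `threshold_rel` of the global maximum and
#' within `min_distance` of a stronger seed; instances are then grown by a
#' marker-controlled watershed of the inverted smoothed intensity,
#' restricted to the Otsu foreground. Each label is connected by
#' construction. The stage is pluggable: an externally produced label map
#' (e.g. from a trained deep segmenter) can be supplied downstream instead
#' via [read_label_map()].
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param sigma_range physical blob-scale range in um, `c(lo, hi)`; for
#'   spheres of radius r the matched LoG sigma is about `r / sqrt(3)`.
#' @param min_distance minimum seed separation, um.
#' @param threshold_rel seeds weaker than this fraction of the strongest
#'   response are discarded.
#' @param n_scales number of scales spanning `sigma_range`.
#' @param refine_half_max trim each instance to the connected support above
#'   half its peak smoothed intensity, removing the brightness-dependent
#'   halo a global threshold leaves around bright nuclei.
#' @return A [label_map()] (empty, with a warning, when no seeds are found).
#' @export
segment_nuclei_instances <- function(stack, channel, sigma_range = c(1.2, 1.8),
                                     min_distance = 2, threshold_rel = 0.1,
                                     n_scales = 3L, refine_half_max = TRUE) {
  arr <- get_channel(stack, channel)
  sp <- unclass(stack$spacing)
  maxval <- 2^stack$bit_depth - 1
  if (max(arr) == min(arr)) {
    warn("constant nuclei channel: no seeds found, returning empty label map")
    return(label_map(array(0L, dim(arr)), stack$spacing))
  }
  fg <- arr >= otsu_threshold(arr, maxval)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_scales))
  resp <- NULL
  sm_lo <- NULL
  for (s in sigmas) {
    sm <- cpp_gauss3d(arr, s / sp[["dz"]], s / sp[["dy"]], s / sp[["dx"]])
    if (is.null(sm_lo)) sm_lo <- sm
    r <- -s^2 * cpp_laplacian3d(sm, sp[["dz"]], sp[["dy"]], sp[["dx"]])
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  dim(resp) <- dim(arr)
  peaks <- cpp_local_maxima(resp, threshold_rel * max(resp))
  if (nrow(peaks) == 0) {
    warn("no LoG seeds found, returning empty label map")
    return(label_map(array(0L, dim(arr)), stack$spacing))
  }
  # greedy minimum-distance suppression, strongest first
  vals <- resp[peaks + 1L] # 0-based rows -> linear via matrix indexing
  ord <- order(vals, decreasing = TRUE)
  pos <- sweep(peaks, 2, c(sp[["dz"]], sp[["dy"]], sp[["dx"]]), `*`)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept)) {
      d2 <- colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2)
      if (min(d2) < min_distance^2) next
    }
    kept <- c(kept, i)
  }
  kept <- kept[fg[peaks[kept, , drop = FALSE] + 1L]] # seeds must be foreground
  if (!length(kept)) {
    warn("all seeds fell outside the foreground, returning empty label map")
    return(label_map(array(0L, dim(arr)), stack$spacing))
  }
  markers <- array(0L, dim(arr))
  markers[peaks[kept, , drop = FALSE] + 1L] <- seq_along(kept)
  lab <- cpp_watershed(-sm_lo, markers, fg)
  # refine on the measured (denoised) intensity, not the detection-scale
  # smoothed field: at blob-detection scale small nuclei lose their
  # plateau and half-of-peak would land well inside the true boundary
  if (refine_half_max) lab <- refine_labels_half_max(lab, arr)
  label_map(lab, stack$spacing)
}

# Trim each watershed region to the voxels above half its peak (smoothed)
# intensity, keeping the connected component that contains the peak.  A
# global threshold makes bright objects look bigger than dim ones (their
# blur halo clears the threshold further out); the per-instance
# full-width-at-half-maximum support removes that bias, so instance
# volumes are comparable across brightness levels.
refine_labels_half_max <- function(lab, intensity) {
  d <- dim(lab)
  idx <- which(lab > 0L)
  if (!length(idx)) return(lab)
  out <- array(0L, d)
  by_label <- split(idx, lab[idx])
  for (lv in names(by_label)) {
    vox <- by_label[[lv]]
    ints <- intensity[vox]
    # robust plateau estimate (upper decile) rather than the noisy max
    peak <- stats::quantile(ints, 0.9, names = FALSE)
    keep <- vox[ints >= 0.5 * peak]
    ai <- arrayInd(keep, d)
    lo <- pmax(apply(ai, 2, min) - 1L, 1L)
    hi <- pmin(apply(ai, 2, max) + 1L, d)
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(ai[, 1] - lo[1] + 1L, ai[, 2] - lo[2] + 1L,
              ai[, 3] - lo[3] + 1L)] <- TRUE
    cc <- cpp_label26(sub)
    peak <- keep[which.max(intensity[keep])]
    pk <- arrayInd(peak, d) - lo + 1L
    comp <- cc[pk[1], pk[2], pk[3]]
    ai_keep <- ai[cc[cbind(ai[, 1] - lo[1] + 1L, ai[, 2] - lo[2] + 1L,
                           ai[, 3] - lo[3] + 1L)] == comp, , drop = FALSE]
    out[ai_keep] <- as.integer(lv)
  }
  out
}

#' Per-nucleus records from a label map
#'
#' One row per label with the intensity-unweighted centroid (um), the
#' physical volume and the mean raw intensity — the tabular hand-off
#' between instance segmentation and density / knot analysis.
#'
#' @param labels a [label_map()].
#' @param stack an [image_stack()] providing the intensity channel.
#' @param channel channel name or index (default `"nuclei"` when present).
#' @return tibble with columns `label`, `cz`, `cy`, `cx` (um),
#'   `volume_um3`, `n_voxels`, `mean_intensity`.
#' @export
extract_nucleus_records <- function(labels, stack = NULL, channel = NULL) {
  stopifnot(inherits(labels, "label_map"))
  idx <- which(labels$data > 0L)
  if (!length(idx)) {
    return(tibble(
      label = integer(0), cz = numeric(0), cy = numeric(0), cx = numeric(0),
      volume_um3 = numeric(0), n_voxels = integer(0),
      mean_intensity = numeric(0)
    ))
  }
  lab <- labels$data[idx]
  pos <- voxel_to_um(arrayInd(idx, dim(labels$data)), labels$spacing)
  inten <- if (!is.null(stack)) {
    if (is.null(channel)) {
      channel <- if ("nuclei" %in% stack$channel_names) "nuclei" else 1L
    }
    get_channel(stack, channel)[idx]
  } else {
    rep(NA_real_, length(idx))
  }
  agg <- unname(rowsum(cbind(pos, inten, 1), group = lab))
  labs <- sort(unique(lab))
  nvox <- agg[, 5]
  tibble(
    label = labs,
    cz = agg[, 1] / nvox,
    cy = agg[, 2] / nvox,
    cx = agg[, 3] / nvox,
    volume_um3 = nvox * voxel_volume(labels$spacing),
    n_voxels = as.integer(nvox),
    mean_intensity = agg[, 4] / nvox
  )
}
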