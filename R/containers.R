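#' Physical voxel spacing
#'
#' Edge lengths of a voxel along the axial (z) and lateral (y, x) directions,
#' in micrometres. Multiphoton stacks are typically anisotropic, e.g. the
#' common acquisition spacing of 0.7 x 0.7 um laterally with a 1.5 um z-step;
#' every geometric quantity in the package is computed in physical units by
#' scaling voxel indices with these lengths.
#'
#' @param dz,dy,dx positive voxel edge lengths in um.
#' @return A `voxel_spacing` object (named numeric of length 3).
#' @examples
#' voxel_spacing(1.5, 0.7, 0.7)
#' @export
voxel_spacing <- function(dz, dy, dx) {
  s <- c(dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("voxel spacing must be strictly positive and finite")
  }
  structure(s, class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("<voxel_spacing> dz=%g dy=%g dx=%g um\n", x[["dz"]], x[["dy"]], x[["dx"]]))
  invisible(x)
}

#' @export
format.voxel_spacing <- function(x, ...) {
  sprintf("(%g, %g, %g) um", x[["dz"]], x[["dy"]], x[["dx"]])
}

is_voxel_spacing <- function(x) inherits(x, "voxel_spacing")

as_voxel_spacing <- function(x) {
  if (is_voxel_spacing(x)) return(x)
  if (is.numeric(x) && length(x) == 3) return(voxel_spacing(x[1], x[2], x[3]))
  abort("cannot interpret object as voxel spacing; use voxel_spacing(dz, dy, dx)")
}

#' Volume of one voxel in cubic micrometres
#' @param spacing a [voxel_spacing()].
#' @return scalar um^3.
#' @export
voxel_volume <- function(spacing) {
  spacing <- as_voxel_spacing(spacing)
  unname(prod(spacing))
}

#' Multichannel 3-D image stack
#'
#' The canonical in-memory representation of an acquired stack: a 4-D array
#' in `(channel, z, y, x)` order with physical voxel spacing and ordered
#' channel names. Intensities are non-negative and nominally 8- or 16-bit.
#'
#' @param data 4-D numeric array `(channel, z, y, x)`, or a 3-D array which
#'   is promoted to a single channel.
#' @param spacing a [voxel_spacing()].
#' @param channel_names character vector, one name per channel.
#' @param bit_depth 8 or 16.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, spacing, channel_names = NULL, bit_depth = 8L) {
  if (length(dim(data)) == 3) {
    dim(data) <- c(1L, dim(data))
  }
  if (length(dim(data)) != 4) abort("image data must be a 3-D or 4-D array")
  if (any(data < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) abort("bit depth must be 8 or 16")
  nc <- dim(data)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) abort("one channel name per channel required")
  structure(
    list(
      data = data,
      spacing = as_voxel_spacing(spacing),
      channel_names = as.character(channel_names),
      bit_depth = as.integer(bit_depth)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d x %d x %d (z,y,x), spacing %s, %d-bit\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
    format(x$spacing), x$bit_depth
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

stack_spatial_dim <- function(stack) dim(stack$data)[-1]

#' Extract one channel of a stack as a 3-D array
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @return 3-D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) {
      abort(sprintf(
        "channel '%s' not found (have: %s)",
        channel, paste(stack$channel_names, collapse = ", ")
      ))
    }
  } else {
    i <- as.integer(channel)
    if (i < 1 || i > dim(stack$data)[1]) abort("channel index out of range")
  }
  arr <- stack$data[i, , , , drop = FALSE]
  dim(arr) <- dim(stack$data)[-1]
  arr
}

#' Binary segmentation mask
#'
#' A 3-D boolean grid `(z, y, x)` with physical voxel spacing; the result of
#' segmenting one structure (villi or vessels) from a stack.
#'
#' @param data 3-D logical (or coercible) array.
#' @param spacing a [voxel_spacing()].
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing) {
  if (length(dim(data)) != 3) abort("mask data must be a 3-D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as_voxel_spacing(spacing)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<binary_mask> %d x %d x %d (z,y,x), %d foreground voxels (%.3g um^3), spacing %s\n",
    d[1], d[2], d[3], sum(x$data), sum(x$data) * voxel_volume(x$spacing),
    format(x$spacing)
  ))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' Labelled instance map
#'
#' A 3-D integer grid where 0 is background and each positive label is one
#' connected instance (typically one nucleus).
#'
#' @param data 3-D integer (or coercible) array of non-negative labels.
#' @param spacing a [voxel_spacing()].
#' @return A `label_map` object.
#' @export
label_map <- function(data, spacing) {
  if (length(dim(data)) != 3) abort("label data must be a 3-D array")
  storage.mode(data) <- "integer"
  if (any(data < 0, na.rm = TRUE)) abort("labels must be non-negative")
  structure(list(data = data, spacing = as_voxel_spacing(spacing)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<label_map> %d x %d x %d (z,y,x), %d labels, spacing %s\n",
    d[1], d[2], d[3], length(setdiff(unique(as.vector(x$data)), 0L)),
    format(x$spacing)
  ))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$data)

#' Number of distinct instances in a label map
#' @param labels a [label_map()].
#' @return integer count of positive labels.
#' @export
n_labels <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  length(setdiff(unique(as.vector(labels$data)), 0L))
}

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    abort("objects have different grid shapes")
  }
  if (max(abs(unclass(a$spacing) - unclass(b$spacing))) > 1e-9) {
    abort("objects have different voxel spacings")
  }
  invisible(TRUE)
}

# physical (z, y, x) positions (um) of voxel indices (1-based matrix/vector)
voxel_to_um <- function(idx, spacing) {
  spacing <- as_voxel_spacing(spacing)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3, byrow = TRUE)
  sweep(idx - 1, 2, unclass(spacing)[c("dz", "dy", "dx")], `*`)
}

# nearest voxel index (1-based) of physical positions
um_to_voxel <- function(pos, spacing) {
  spacing <- as_voxel_spacing(spacing)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3, byrow = TRUE)
  round(sweep(pos, 2, unclass(spacing)[c("dz", "dy", "dx")], `/`)) + 1
}
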