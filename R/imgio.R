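#' Read a multichannel 3-D stack from TIFF
#'
#' Reads a multi-page TIFF into an [image_stack()]. Voxel spacing is taken,
#' in order of preference, from (1) a `<path>.meta.json` sidecar written by
#' [write_stack()], (2) ImageJ-style TIFF metadata (`x.resolution` /
#' `y.resolution` tags for the lateral spacing plus a `spacing=` entry in the
#' image description for the z-step), (3) `spacing_override`. Missing spacing
#' is an error, never silently defaulted. A plain 3-D file becomes a
#' single-channel stack; multichannel files interleave channels fastest
#' within each z-plane (the ImageJ hyperstack convention).
#'
#' @param path TIFF file path.
#' @param spacing_override optional [voxel_spacing()] used when the file
#'   carries no spacing metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample
  if (is.null(bits)) bits <- 8L
  if (!bits %in% c(8L, 16L)) {
    abort(sprintf("unsupported bit depth: %s (only 8 and 16 bit supported)", bits))
  }

  meta <- read_stack_sidecar(path)
  n_channels <- 1L
  channel_names <- NULL
  spacing <- NULL

  if (!is.null(meta)) {
    spacing <- voxel_spacing(meta$spacing[1], meta$spacing[2], meta$spacing[3])
    n_channels <- as.integer(meta$channels)
    channel_names <- meta$channel_names
  } else {
    tagmeta <- spacing_from_tiff_info(info)
    if (!is.null(tagmeta$spacing)) spacing <- tagmeta$spacing
    if (!is.null(tagmeta$channels)) n_channels <- tagmeta$channels
  }
  if (is.null(spacing)) {
    if (is.null(spacing_override)) {
      abort(paste0(
        "no voxel spacing found in TIFF metadata or sidecar for '", path,
        "'; pass spacing_override = voxel_spacing(dz, dy, dx)"
      ))
    }
    spacing <- as_voxel_spacing(spacing_override)
  }

  npages <- length(pages)
  if (npages %% n_channels != 0) {
    abort("page count is not a multiple of the channel count")
  }
  nz <- npages %/% n_channels
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  data <- array(0, dim = c(n_channels, nz, ny, nx))
  for (p in seq_len(npages)) {
    ch <- (p - 1L) %% n_channels + 1L
    z <- (p - 1L) %/% n_channels + 1L
    data[ch, z, , ] <- pages[[p]]
  }
  image_stack(data, spacing, channel_names = channel_names,
              bit_depth = as.integer(bits))
}

#' Write an image stack to TIFF (with spacing sidecar)
#'
#' Pages are written channel-fastest within each z-plane. Because the
#' available TIFF writer cannot emit resolution tags, the voxel spacing,
#' channel count and channel names are stored in a `<path>.meta.json`
#' sidecar which [read_stack()] picks up, so a write/read round trip
#' preserves both voxels and spacing exactly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  maxval <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      pages[[p]] <- stack$data[ch, z, , ] / maxval
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  meta <- list(
    spacing = as.numeric(unclass(stack$spacing)),
    channels = d[1],
    channel_names = stack$channel_names,
    bit_depth = stack$bit_depth
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

read_stack_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  m <- jsonlite::read_json(sp, simplifyVector = TRUE)
  m$channel_names <- as.character(m$channel_names)
  m
}

# parse ImageJ-style spacing out of readTIFF info attributes
spacing_from_tiff_info <- function(info) {
  out <- list(spacing = NULL, channels = NULL)
  desc <- info$description
  dz <- dy <- dx <- NA_real_
  if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
      info$x.resolution > 0) {
    dx <- 1 / info$x.resolution
  }
  if (!is.null(info$y.resolution) && is.finite(info$y.resolution) &&
      info$y.resolution > 0) {
    dy <- 1 / info$y.resolution
  } else {
    dy <- dx
  }
  if (!is.null(desc) && is.character(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) dz <- as.numeric(m[2])
    mc <- regmatches(desc, regexec("channels=([0-9]+)", desc))[[1]]
    if (length(mc) == 2) out$channels <- as.integer(mc[2])
  }
  if (all(is.finite(c(dz, dy, dx)))) out$spacing <- voxel_spacing(dz, dy, dx)
  out
}

#' Write a binary mask as NRRD
#'
#' Writes the mask as an attached-header NRRD file (`uint8`, raw encoding)
#' with per-axis spacings in the header, fastest axis first (x, y, z) to
#' match the dialect FIJI exports and 3Dslicer imports. A read-back with
#' [read_mask_nrrd()] reproduces the boolean grid and spacing exactly.
#'
#' @param mask a [binary_mask()].
#' @param path output path (conventionally `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_mask_nrrd <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  sp <- unclass(mask$spacing)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c(
    "NRRD0004",
    "# complete NRRD (attached header)",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[3], d[2], d[1]), # x y z, fastest first
    sprintf("spacings: %.10g %.10g %.10g", sp[["dx"]], sp[["dy"]], sp[["dz"]]),
    "encoding: raw",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  # permute (z,y,x) -> x fastest
  payload <- as.integer(aperm(mask$data, c(3, 2, 1)))
  writeBin(as.raw(payload), con)
  invisible(path)
}

#' Write a label map as NRRD (uint16)
#' @param labels a [label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_nrrd <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (max(labels$data) > 65535L) abort("labels exceed uint16 range")
  d <- dim(labels$data)
  sp <- unclass(labels$spacing)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c(
    "NRRD0004",
    "type: uint16",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[3], d[2], d[1]),
    sprintf("spacings: %.10g %.10g %.10g", sp[["dx"]], sp[["dy"]], sp[["dz"]]),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  payload <- as.integer(aperm(labels$data, c(3, 2, 1)))
  writeBin(payload, con, size = 2L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# slurp an NRRD file: parse header fields and return the integer payload
# array in (z, y, x) order plus the header field list
parse_nrrd <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line (\n\n); tolerate \r\n
  split_at <- NA_integer_
  for (i in seq_len(length(bytes) - 1L)) {
    if (bytes[i] == as.raw(10L)) {
      j <- i + 1L
      if (bytes[j] == as.raw(13L) && j < length(bytes)) j <- j + 1L
      if (bytes[j] == as.raw(10L)) { split_at <- j; break }
    }
  }
  if (is.na(split_at)) abort("malformed NRRD: no header/payload separator")
  header <- strsplit(rawToChar(bytes[seq_len(split_at)]), "\r?\n")[[1]]
  payload <- bytes[seq.int(split_at + 1L, length(bytes))]
  if (!grepl("^NRRD", header[1])) abort("not an NRRD file")
  fields <- list()
  for (line in header[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) abort("only 3-D NRRD volumes are supported")
  type <- tolower(fields$type)
  bytes_per <- switch(type,
    "uint8" = , "uchar" = , "unsigned char" = , "int8" = , "signed char" = 1L,
    "uint16" = , "unsigned short" = , "short" = , "int16" = 2L,
    "uint32" = , "unsigned int" = , "int" = , "int32" = 4L,
    abort(sprintf("unsupported NRRD type: %s", type))
  )
  signed <- type %in% c("int8", "signed char", "short", "int16", "int", "int32")
  enc <- tolower(fields$encoding %||% "raw")
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  n <- prod(sizes)
  if (length(payload) < n * bytes_per) abort("NRRD payload truncated")
  endian <- if (identical(tolower(fields$endian %||% "little"), "big")) "big" else "little"
  vals <- readBin(payload, what = "integer", n = n, size = bytes_per,
                  signed = if (bytes_per >= 4L) TRUE else signed, endian = endian)
  arr <- aperm(array(vals, dim = sizes), c(3, 2, 1)) # x-fastest -> (z, y, x)
  list(data = arr, fields = fields)
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields$spacings)) {
    sxyz <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    return(voxel_spacing(sxyz[3], sxyz[2], sxyz[1]))
  }
  if (!is.null(fields[["space directions"]])) {
    nums <- as.numeric(regmatches(
      fields[["space directions"]],
      gregexpr("[0-9.eE+-]+", fields[["space directions"]])
    )[[1]])
    m <- matrix(nums, nrow = 3, byrow = TRUE)
    diag_sp <- sqrt(rowSums(m^2))
    return(voxel_spacing(diag_sp[3], diag_sp[2], diag_sp[1]))
  }
  abort("NRRD header carries no spacings; spacing is never defaulted")
}

#' Read a binary mask from NRRD
#'
#' Supports attached-header NRRD with `raw` or `gzip` encoding and integer
#' types; voxel values are binarized (non-zero is foreground). Axes are
#' assumed fastest-first (x, y, z), the dialect written by FIJI and by
#' [write_mask_nrrd()].
#'
#' @param path NRRD file path.
#' @return A [binary_mask()].
#' @export
read_mask_nrrd <- function(path) {
  p <- parse_nrrd(path)
  binary_mask(p$data != 0, nrrd_spacing(p$fields))
}

#' Read a label map from TIFF or NRRD
#'
#' Accepts externally produced instance maps (e.g. exported from a trained
#' nucleus segmenter) so the internal instance segmentation can be bypassed.
#'
#' @param path file path (`.nrrd` or TIFF).
#' @param spacing_override optional spacing when the file carries none.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, spacing_override = NULL) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    # re-read preserving integer values
    m <- read_label_nrrd_int(path)
    return(m)
  }
  st <- read_stack(path, spacing_override = spacing_override)
  arr <- get_channel(st, 1)
  storage.mode(arr) <- "integer"
  label_map(arr, st$spacing)
}

read_label_nrrd_int <- function(path) {
  p <- parse_nrrd(path)
  label_map(p$data, nrrd_spacing(p$fields))
}

#' Write a morphometry report to CSV or JSON
#'
#' One row per analysed image with the eight canonical metric columns
#' (`villous_volume_um3`, `surface_area_um2`, `sa_vol_per_um`,
#' `nuclear_density_per_mm3`, `knot_fraction_pct`, `vascular_fraction_pct`,
#' `branchpoint_density_per_um`, `mean_tortuosity`).
#'
#' @param report a morphometry report tibble (see [run_quantification()]).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  report <- as.data.frame(report)
  if (format == "csv") {
    write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a morphometry report back
#' @param path file written by [write_report()].
#' @param format `"csv"` or `"json"`.
#' @return tibble.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    as_tibble(read.csv(path, stringsAsFactors = FALSE))
  } else {
    as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

report_metric_columns <- function() {
  c(
    "villous_volume_um3", "surface_area_um2", "sa_vol_per_um",
    "nuclear_density_per_mm3", "knot_fraction_pct", "vascular_fraction_pct",
    "branchpoint_density_per_um", "mean_tortuosity"
  )
}
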