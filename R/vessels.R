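#' Skeletonize a vessel mask to a one-voxel-wide centreline set
#'
#' Topology-preserving 3-D thinning: simple points (whose deletion provably
#' leaves connectivity, tunnels and cavities unchanged) are removed in six
#' directional sub-iterations with sequential re-checking, retaining curve
#' endpoints, until stability. Because the topological guarantees of
#' thinning assume isotropic connectivity, anisotropic masks are first
#' resampled to an isotropic grid at the finest spacing (trilinear,
#' threshold 0.5); all reported lengths remain in physical um.
#'
#' @param mask a non-empty [binary_mask()].
#' @return A `skeleton3d` object: the skeleton voxel set and the
#'   (isotropic) mask it was thinned from.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) abort("cannot skeletonize an empty mask")
  sp <- unclass(mask$spacing)
  dmin <- min(sp)
  if (max(sp) / dmin > 1.01) {
    d <- dim(mask$data)
    n2 <- pmax(2L, as.integer(round((d - 1) * sp[c("dz", "dy", "dx")] / dmin)) + 1L)
    f <- dmin / sp[c("dz", "dy", "dx")]
    vol <- cpp_resample3d(mask$data * 1.0, n2[1], n2[2], n2[3],
                          f[1], f[2], f[3])
    iso <- array(vol >= 0.5, dim = n2)
  } else {
    dmin <- sp[["dz"]] # honour the actual (iso) spacing
    iso <- mask$data
  }
  skel <- array(cpp_thin3d(iso), dim = dim(iso))
  structure(
    list(voxels = skel, mask_iso = iso,
         spacing = voxel_spacing(dmin, dmin, dmin),
         orig_spacing = mask$spacing),
    class = "skeleton3d"
  )
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %d skeleton voxels on %s grid, spacing %s\n",
              sum(x$voxels), paste(dim(x$voxels), collapse = " x "),
              format(x$spacing)))
  invisible(x)
}

# 26-neighbour count within a boolean array, per voxel
neighbour_count26 <- function(S) {
  d <- dim(S)
  cnt <- array(0L, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
    src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
    src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
    cnt[src_z, src_y, src_x] <- cnt[src_z, src_y, src_x] +
      S[src_z + dz, src_y + dy, src_x + dx]
  }
  cnt
}

#' Build the vessel network graph from a skeleton
#'
#' Skeleton voxels are classified by their 26-neighbour count (1 =
#' endpoint, >= 3 = branch voxel); 26-adjacent branch voxels merge into a
#' single branchpoint node at their centroid; paths between nodes are
#' traced into polyline edges with physical arc length, chord length,
#' tortuosity and a vessel diameter profile (twice the Euclidean distance
#' transform of the mask sampled along the polyline). Spurious short spurs
#' — endpoint edges shorter than `prune_spur_factor` times their local mean
#' diameter, the hair artefacts thinning produces on voxelized tubes — are
#' pruned and the graph rebuilt.
#'
#' @param skeleton a `skeleton3d` from [skeletonize()], or a
#'   [binary_mask()] (skeletonized first).
#' @param prune_spur_factor prune endpoint edges shorter than this multiple
#'   of their mean diameter (0 disables).
#' @param merge_branch_factor merge branchpoint nodes closer than this
#'   multiple of the network mean diameter into one junction (thinning can
#'   split one anatomical junction of a thick vessel into two nearby
#'   branch clusters; 0 disables).
#' @return A `skeleton_graph`: list with `nodes` and `edges` tibbles,
#'   polylines and diameter profiles (all positions/lengths in um).
#' @export
build_network <- function(skeleton, prune_spur_factor = 1,
                          merge_branch_factor = 1.5) {
  if (inherits(skeleton, "binary_mask")) skeleton <- skeletonize(skeleton)
  stopifnot(inherits(skeleton, "skeleton3d"))
  edt <- cpp_edt(skeleton$mask_iso, skeleton$spacing[["dz"]],
                 skeleton$spacing[["dy"]], skeleton$spacing[["dx"]])
  S <- skeleton$voxels
  for (iter in 1:3) {
    g <- trace_network(S, skeleton$spacing, edt)
    if (prune_spur_factor <= 0) break
    # vessel-scale reference: pooled mean diameter of the whole network
    # (spur tips sit in thin cap regions, so their local diameter is not a
    # usable scale)
    net_diam <- mean(unlist(g$profiles))
    spur <- g$edges$terminal &
      (g$edges$from_kind == "branchpoint" | g$edges$to_kind == "branchpoint") &
      g$edges$arc_length_um < prune_spur_factor * net_diam
    spur[is.na(spur)] <- FALSE
    if (!any(spur)) break
    # delete spur path voxels and their endpoint voxel, keep branch clusters
    for (e in which(spur)) {
      vox <- g$edge_voxels[[e]]
      S[vox[!g$is_branch_voxel[vox]]] <- FALSE
    }
  }
  g <- merge_close_branchpoints(g, merge_branch_factor)
  structure(
    list(nodes = g$nodes, edges = g$edges, polylines = g$polylines,
         profiles = g$profiles, spacing = skeleton$spacing,
         n_components = g$n_components),
    class = "skeleton_graph"
  )
}

# single-linkage merge of branchpoint nodes closer than
# factor * network mean diameter; connecting micro-edges are absorbed
merge_close_branchpoints <- function(g, factor) {
  if (factor <= 0) return(g)
  bp <- which(g$nodes$kind == "branchpoint")
  if (length(bp) < 2) return(g)
  thr <- factor * mean(unlist(g$profiles))
  pos <- as.matrix(g$nodes[bp, c("cz", "cy", "cx")])
  d <- as.matrix(stats::dist(pos))
  adj <- d < thr
  grp <- seq_along(bp)
  repeat {
    changed <- FALSE
    for (i in seq_along(bp)) {
      m <- min(grp[adj[i, ]])
      if (m < grp[i]) { grp[grp == grp[i]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  if (length(unique(grp)) == length(bp)) return(g)
  # representative id per group; reposition at member centroid
  node_map <- g$nodes$node_id
  for (gr in unique(grp)) {
    members <- bp[grp == gr]
    rep_id <- min(members)
    node_map[members] <- rep_id
    g$nodes[g$nodes$node_id == rep_id, c("cz", "cy", "cx")] <-
      as.list(colMeans(g$nodes[members, c("cz", "cy", "cx")]))
  }
  g$edges$from <- node_map[g$edges$from]
  g$edges$to <- node_map[g$edges$to]
  # drop micro-edges now internal to a merged junction
  internal <- g$edges$from == g$edges$to &
    g$edges$from_kind == "branchpoint" & g$edges$to_kind == "branchpoint" &
    g$edges$arc_length_um < thr
  keep <- !internal
  g$edges <- g$edges[keep, , drop = FALSE]
  g$edges$edge_id <- seq_len(nrow(g$edges))
  g$polylines <- g$polylines[keep]
  g$profiles <- g$profiles[keep]
  kept_nodes <- sort(unique(c(g$edges$from, g$edges$to,
                              g$nodes$node_id[g$nodes$kind != "branchpoint"])))
  g$nodes <- g$nodes[g$nodes$node_id %in% c(kept_nodes, node_map), , drop = FALSE]
  g$nodes <- g$nodes[g$nodes$node_id %in% unique(node_map) |
                       g$nodes$kind != "branchpoint", , drop = FALSE]
  # recompute chord/tortuosity for edges whose nodes moved
  posn <- g$nodes
  for (e in seq_len(nrow(g$edges))) {
    p1 <- as.numeric(posn[posn$node_id == g$edges$from[e], c("cz", "cy", "cx")])
    p2 <- as.numeric(posn[posn$node_id == g$edges$to[e], c("cz", "cy", "cx")])
    pl <- g$polylines[[e]]
    pl[1, ] <- p1
    pl[nrow(pl), ] <- p2
    g$polylines[[e]] <- pl
    steps <- sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2))
    g$edges$arc_length_um[e] <- sum(steps)
    g$edges$chord_length_um[e] <- sqrt(sum((p2 - p1)^2))
    g$edges$tortuosity[e] <- if (g$edges$chord_length_um[e] > 1e-9) {
      g$edges$arc_length_um[e] / g$edges$chord_length_um[e]
    } else NA_real_
  }
  g
}

# moving-average smoothing of a traced polyline (ends pinned): voxel-to-
# voxel tracing zig-zags on curved paths and inflates arc length by several
# percent; a short window recovers the smooth centreline
smooth_polyline <- function(pos, window = 5L) {
  n <- nrow(pos)
  if (n <= 3 || window < 2) return(pos)
  half <- window %/% 2
  out <- pos
  for (i in 2:(n - 1)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i, ] <- colMeans(pos[lo:hi, , drop = FALSE])
  }
  out
}

# core graph tracing on a skeleton voxel array
trace_network <- function(S, spacing, edt) {
  d <- dim(S)
  sp <- unclass(spacing)[c("dz", "dy", "dx")]
  cnt <- neighbour_count26(S)
  branch <- S & cnt >= 3L
  endpoint <- S & cnt == 1L
  isolated <- S & cnt == 0L
  comp <- cpp_label26(S)
  n_components <- max(comp)

  # nodes: merged branch clusters, then endpoints
  bl <- cpp_label26(branch)
  n_branch <- max(bl)
  node_of <- array(0L, d)
  node_pos <- list()
  node_kind <- character(0)
  if (n_branch > 0) {
    bidx <- which(bl > 0L)
    pos <- voxel_to_um(arrayInd(bidx, d), spacing)
    agg <- rowsum(cbind(pos, 1), group = bl[bidx])
    for (i in seq_len(n_branch)) {
      node_pos[[i]] <- agg[i, 1:3] / agg[i, 4]
      node_kind[i] <- "branchpoint"
    }
    node_of[bidx] <- bl[bidx]
  }
  eidx <- which(endpoint | isolated)
  for (i in seq_along(eidx)) {
    id <- n_branch + i
    node_of[eidx[i]] <- id
    node_pos[[id]] <- as.numeric(voxel_to_um(arrayInd(eidx[i], d), spacing))
    node_kind[id] <- "endpoint"
  }
  n_nodes <- length(node_pos)

  # precompute 26-neighbour linear offsets
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]

  nbrs_of <- function(i) {
    ai <- arrayInd(i, d)
    nz <- ai[1] + offs[, 1]; ny <- ai[2] + offs[, 2]; nx <- ai[3] + offs[, 3]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    j <- nz[ok] + d[1] * (ny[ok] - 1) + d[1] * d[2] * (nx[ok] - 1)
    j[S[j]]
  }

  visited <- array(FALSE, d)
  edges <- list()
  polylines <- list()
  profiles <- list()
  edge_voxels <- list()
  seen_pair <- character(0)

  node_voxels <- which(node_of > 0L)
  for (v in node_voxels) {
    for (w in nbrs_of(v)) {
      if (node_of[w] > 0L) {
        # direct node-node adjacency (only across different nodes, once)
        if (node_of[w] == node_of[v]) next
        key <- paste(sort(c(v, w)), collapse = "-")
        if (key %in% seen_pair) next
        seen_pair <- c(seen_pair, key)
        chain <- c(v, w)
      } else {
        if (visited[w]) next
        chain <- c(v, w)
        visited[w] <- TRUE
        prev <- v
        cur <- w
        repeat {
          nx_ <- nbrs_of(cur)
          nx_ <- nx_[nx_ != prev]
          node_hit <- nx_[node_of[nx_] > 0L & node_of[nx_] != node_of[prev]]
          if (length(node_hit)) {
            chain <- c(chain, min(node_hit))
            break
          }
          nx_ <- nx_[!visited[nx_] & node_of[nx_] == 0L]
          if (!length(nx_)) break # dead end into visited voxels
          nxt <- min(nx_)
          visited[nxt] <- TRUE
          chain <- c(chain, nxt)
          prev <- cur
          cur <- nxt
        }
      }
      last <- chain[length(chain)]
      if (node_of[last] == 0L) next # aborted trace (rejoined a visited path)
      edges[[length(edges) + 1L]] <- c(node_of[v], node_of[last])
      polyvox <- chain
      edge_voxels[[length(edges)]] <- polyvox
      pos <- voxel_to_um(arrayInd(polyvox, d), spacing)
      # polyline endpoints coincide with node positions
      pos[1, ] <- node_pos[[node_of[v]]]
      pos[nrow(pos), ] <- node_pos[[node_of[last]]]
      polylines[[length(edges)]] <- smooth_polyline(pos)
      profiles[[length(edges)]] <- 2 * edt[polyvox]
    }
  }

  # closed loops with no node voxel at all: anchor a loop node
  remaining <- which(S & !visited & node_of == 0L & cnt == 2L)
  for (v0 in remaining) {
    if (visited[v0]) next
    chain <- v0
    visited[v0] <- TRUE
    prev <- v0
    nb0 <- nbrs_of(v0)
    if (!length(nb0)) next
    cur <- min(nb0)
    while (cur != v0) {
      visited[cur] <- TRUE
      chain <- c(chain, cur)
      nx_ <- nbrs_of(cur)
      nx_ <- nx_[nx_ != prev]
      if (!length(nx_)) break
      prev <- cur
      cur <- min(nx_)
    }
    chain <- c(chain, v0)
    id <- length(node_pos) + 1L
    node_pos[[id]] <- as.numeric(voxel_to_um(arrayInd(v0, d), spacing))
    node_kind[id] <- "loop"
    n_nodes <- id
    edges[[length(edges) + 1L]] <- c(id, id)
    edge_voxels[[length(edges)]] <- chain
    polylines[[length(edges)]] <- smooth_polyline(
      voxel_to_um(arrayInd(chain, d), spacing)
    )
    profiles[[length(edges)]] <- 2 * edt[chain]
  }

  nodes <- if (n_nodes > 0) {
    posm <- do.call(rbind, node_pos)
    tibble(node_id = seq_len(n_nodes), kind = node_kind,
           cz = posm[, 1], cy = posm[, 2], cx = posm[, 3])
  } else {
    tibble(node_id = integer(0), kind = character(0),
           cz = numeric(0), cy = numeric(0), cx = numeric(0))
  }

  ne <- length(edges)
  arc <- chord <- tort <- mdi <- mndi <- cvdi <- numeric(ne)
  npr <- integer(ne)
  short_flag <- logical(ne)
  from <- to <- integer(ne)
  for (e in seq_len(ne)) {
    from[e] <- edges[[e]][1]; to[e] <- edges[[e]][2]
    pl <- polylines[[e]]
    steps <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                             pl[-nrow(pl), , drop = FALSE])^2))
    arc[e] <- sum(steps)
    chord[e] <- sqrt(sum((pl[nrow(pl), ] - pl[1, ])^2))
    tort[e] <- if (chord[e] > 1e-9) arc[e] / chord[e] else NA_real_
    prof <- profiles[[e]]
    core <- if (length(prof) > 4) prof[3:(length(prof) - 2)] else numeric(0)
    short_flag[e] <- length(prof) < 5
    use <- if (length(core)) core else prof
    mdi[e] <- mean(use)
    mndi[e] <- min(use)
    cvdi[e] <- if (length(use) > 1 && mean(use) > 0) stats::sd(use) / mean(use) else NA_real_
    npr[e] <- length(use)
  }
  kind_of <- function(id) ifelse(id >= 1 & id <= n_nodes, node_kind[id], NA)
  edges_tbl <- tibble(
    edge_id = seq_len(ne), from = from, to = to,
    from_kind = kind_of(from), to_kind = kind_of(to),
    terminal = kind_of(from) == "endpoint" | kind_of(to) == "endpoint",
    arc_length_um = arc, chord_length_um = chord, tortuosity = tort,
    mean_diameter_um = mdi, min_diameter_um = mndi, cv_diameter = cvdi,
    n_profile = npr, short_flag = short_flag
  )
  is_branch_voxel <- array(FALSE, d)
  is_branch_voxel[which(node_of > 0L & branch)] <- TRUE
  list(nodes = nodes, edges = edges_tbl, polylines = polylines,
       profiles = profiles, edge_voxels = edge_voxels,
       is_branch_voxel = is_branch_voxel, n_components = n_components)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  nb <- sum(x$nodes$kind == "branchpoint")
  ne <- sum(x$nodes$kind == "endpoint")
  cat(sprintf(
    "<skeleton_graph> %d branchpoint(s), %d endpoint(s), %d edge(s), total length %.1f um\n",
    nb, ne, nrow(x$edges), sum(x$edges$arc_length_um)
  ))
  invisible(x)
}

#' Tortuosity of a vessel segment
#'
#' Arc length of the centreline divided by the straight-line (chord)
#' distance between its two nodes; >= 1 by construction, undefined (NA)
#' for closed loops whose endpoints coincide.
#'
#' @param edge one row of a `skeleton_graph` edge table (or a list with
#'   `arc_length_um` and `chord_length_um`).
#' @return dimensionless ratio, or NA for loops.
#' @export
segment_tortuosity <- function(edge) {
  if (is.data.frame(edge) && nrow(edge) != 1) {
    abort("segment_tortuosity expects a single edge")
  }
  arc <- edge$arc_length_um
  chord <- edge$chord_length_um
  if (chord <= 1e-9) return(NA_real_)
  arc / chord
}

#' Mean tortuosity of a network
#'
#' Tortuosity is defined between branchpoints; endpoint-terminated
#' segments are excluded by default (includable with
#' `include_terminal = TRUE`); undefined loop segments are always
#' excluded and counted separately.
#'
#' @param graph a `skeleton_graph`.
#' @param include_terminal include endpoint-terminated segments.
#' @return list with `mean_tortuosity`, `n_segments`, `n_undefined`.
#' @export
mean_tortuosity <- function(graph, include_terminal = FALSE) {
  e <- graph$edges
  defined <- !is.na(e$tortuosity)
  use <- defined & (include_terminal | !e$terminal)
  if (!any(use) && any(defined)) use <- defined # endpoint-only networks
  list(
    mean_tortuosity = if (any(use)) mean(e$tortuosity[use]) else NA_real_,
    n_segments = sum(use),
    n_undefined = sum(!defined)
  )
}

#' Branchpoint density of a network
#'
#' Number of branchpoint nodes divided by the total network (centreline
#' arc) length, in 1/um.
#'
#' @param graph a `skeleton_graph`.
#' @return density in 1/um.
#' @export
branchpoint_density <- function(graph) {
  total <- sum(graph$edges$arc_length_um)
  if (total <= 0) abort("network has zero length")
  sum(graph$nodes$kind == "branchpoint") / total
}

#' Diameter summaries of a network
#'
#' Per-edge and whole-network summaries of the diameter profiles, with the
#' two polyline voxels adjacent to each node excluded (junction inflation
#' guard); edges shorter than 5 profile voxels are flagged and report a
#' mean only.
#'
#' @param graph a `skeleton_graph`.
#' @return list with `per_edge` (tibble) and `network`
#'   (mean/min/cv over all retained profile samples).
#' @export
diameter_stats <- function(graph) {
  e <- graph$edges
  per_edge <- dplyr::select(e, "edge_id", "mean_diameter_um",
                            "min_diameter_um", "cv_diameter", "n_profile",
                            "short_flag")
  pooled <- unlist(lapply(graph$profiles, function(p) {
    if (length(p) > 4) p[3:(length(p) - 2)] else p
  }))
  network <- list(
    mean_diameter_um = mean(pooled),
    min_diameter_um = min(pooled),
    cv_diameter = stats::sd(pooled) / mean(pooled)
  )
  list(per_edge = per_edge, network = network)
}

#' Export a network as node/edge CSV tables
#' @param graph a `skeleton_graph`.
#' @param nodes_path,edges_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_network_csv <- function(graph, nodes_path, edges_path) {
  write.csv(as.data.frame(graph$nodes), nodes_path, row.names = FALSE)
  e <- as.data.frame(dplyr::select(graph$edges, -dplyr::any_of(character(0))))
  write.csv(e, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Export network polylines as a legacy-VTK file
#'
#' ASCII VTK PolyData with one polyline per edge and tortuosity /
#' mean-diameter cell data; loadable in 3Dslicer or ParaView, keeping the
#' established slicer-based toolchain reachable. Points are written (x, y,
#' z) in um.
#'
#' @param graph a `skeleton_graph`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_network_vtk <- function(graph, path) {
  pls <- graph$polylines
  npts <- sum(vapply(pls, nrow, integer(1)))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "vessel centreline network (um)",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d float", npts)
  ), con)
  for (pl in pls) {
    # (z,y,x) -> x y z
    apply(pl, 1, function(p) writeLines(sprintf("%.4f %.4f %.4f",
                                                p[3], p[2], p[1]), con))
  }
  sizes <- vapply(pls, nrow, integer(1))
  writeLines(sprintf("LINES %d %d", length(pls), sum(sizes + 1L)), con)
  offset <- 0L
  for (s in sizes) {
    writeLines(paste(c(s, seq.int(offset, offset + s - 1L)), collapse = " "), con)
    offset <- offset + s
  }
  writeLines(sprintf("CELL_DATA %d", length(pls)), con)
  writeLines(c("SCALARS tortuosity float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6f", ifelse(is.na(graph$edges$tortuosity), -1,
                                    graph$edges$tortuosity)), con)
  writeLines(c("SCALARS mean_diameter_um float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6f", graph$edges$mean_diameter_um), con)
  invisible(path)
}
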