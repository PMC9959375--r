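# independent reference implementations used as test oracles

# O(n^2) dense-matrix DBSCAN with the same semantics as the package
# implementation (inclusive eps, self counted, border point claimed by its
# lowest-index core neighbour, cluster ids in order of first core point),
# written as a separate route: full distance matrix + union-find
dbscan_brute <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(pts))
  adj <- D <= eps
  n_nb <- rowSums(adj) # self included on the diagonal
  core <- n_nb >= min_pts
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(core)) for (j in which(core & adj[i, ])) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  cl <- integer(n)
  next_id <- 0L
  root_id <- integer(n)
  for (i in seq_len(n)) {
    if (!core[i]) next
    r <- find(i)
    if (root_id[r] == 0L) {
      next_id <- next_id + 1L
      root_id[r] <- next_id
    }
    cl[i] <- root_id[r]
  }
  for (i in seq_len(n)) {
    if (core[i]) next
    cores <- which(core & adj[i, ])
    if (length(cores)) cl[i] <- cl[min(cores)]
  }
  cl
}

# canonical relabelling so partitions can be compared up to label names
canonical_labels <- function(cl) {
  out <- integer(length(cl))
  map <- integer(0)
  nxt <- 0L
  for (i in seq_along(cl)) {
    if (cl[i] == 0L) next
    key <- as.character(cl[i])
    if (is.na(map[key]) || is.null(map[key]) || !key %in% names(map)) {
      nxt <- nxt + 1L
      map[key] <- nxt
    }
    out[i] <- map[[key]]
  }
  out
}

# uniform sample inside a solid ellipsoid with given semi-axes (rows are
# (z, y, x) positions); used as the analytic shape-index oracle point set
ellipsoid_cloud <- function(semi_axes, n = 4000, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    cand <- matrix(runif(3 * n, -1, 1), ncol = 3)
    keep <- rowSums(cand^2) <= 1
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), ]
  sweep(pts, 2, semi_axes, `*`)
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
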