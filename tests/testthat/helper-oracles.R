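# Brute-force texture-matrix oracles, written independently of the package
# kernels: plain R loops over voxels, neighbours and runs.

oracle_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

oracle_directions13 <- function() {
  g <- oracle_offsets(26L)
  # keep one representative of each +/- pair (first nonzero component > 0)
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

# Zones: connected components of equal level, enumerated by repeated BFS.
oracle_glszm <- function(lev, n_levels, connectivity = 26L) {
  d <- dim(lev)
  off <- oracle_offsets(connectivity)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (lev[i, j, k] == 0 || seen[i, j, k]) next
    lab <- lev[i, j, k]
    queue <- matrix(c(i, j, k), ncol = 3)
    seen[i, j, k] <- TRUE
    size <- 0L
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (o in seq_len(nrow(off))) {
        p <- cur + off[o, ]
        if (any(p < 1) || any(p > d)) next
        if (!seen[p[1], p[2], p[3]] && lev[p[1], p[2], p[3]] == lab) {
          seen[p[1], p[2], p[3]] <- TRUE
          queue <- rbind(queue, p)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lab, size)
  }
  zs <- do.call(rbind, zones)
  P <- matrix(0L, n_levels, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) P[zs[r, 1], zs[r, 2]] <- P[zs[r, 1], zs[r, 2]] + 1L
  P
}

oracle_gldm <- function(lev, n_levels, alpha = 0, connectivity = 26L) {
  d <- dim(lev)
  off <- oracle_offsets(connectivity)
  P <- matrix(0L, n_levels, nrow(off) + 1L)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (lev[i, j, k] == 0) next
    dep <- 1L
    for (o in seq_len(nrow(off))) {
      p <- c(i, j, k) + off[o, ]
      if (any(p < 1) || any(p > d)) next
      pl <- lev[p[1], p[2], p[3]]
      if (pl != 0 && abs(pl - lev[i, j, k]) <= alpha) dep <- dep + 1L
    }
    P[lev[i, j, k], dep] <- P[lev[i, j, k], dep] + 1L
  }
  P
}

# Runs: walk every maximal straight same-level segment per direction.
oracle_glrlm <- function(lev, n_levels) {
  d <- dim(lev)
  dirs <- oracle_directions13()
  mx <- max(d)
  out <- array(0L, dim = c(n_levels, mx, nrow(dirs)))
  for (a in seq_len(nrow(dirs))) {
    dv <- dirs[a, ]
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      v <- lev[i, j, k]
      if (v == 0) next
      prev <- c(i, j, k) - dv
      if (all(prev >= 1) && all(prev <= d) &&
          lev[prev[1], prev[2], prev[3]] == v) next
      len <- 1L
      cur <- c(i, j, k) + dv
      while (all(cur >= 1) && all(cur <= d) &&
             lev[cur[1], cur[2], cur[3]] == v) {
        len <- len + 1L
        cur <- cur + dv
      }
      out[v, len, a] <- out[v, len, a] + 1L
    }
  }
  out
}

# Symmetric co-occurrences: loop over all voxel pairs per direction.
oracle_glcm <- function(lev, n_levels) {
  d <- dim(lev)
  dirs <- oracle_directions13()
  out <- array(0L, dim = c(n_levels, n_levels, nrow(dirs)))
  for (a in seq_len(nrow(dirs))) {
    dv <- dirs[a, ]
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      v <- lev[i, j, k]
      if (v == 0) next
      p <- c(i, j, k) + dv
      if (any(p < 1) || any(p > d)) next
      w <- lev[p[1], p[2], p[3]]
      if (w == 0) next
      out[v, w, a] <- out[v, w, a] + 1L
      out[w, v, a] <- out[w, v, a] + 1L
    }
  }
  out
}

oracle_ngtdm <- function(lev, n_levels) {
  d <- dim(lev)
  off <- oracle_offsets(26L)
  n_i <- integer(n_levels); s_i <- numeric(n_levels)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- lev[i, j, k]
    if (v == 0) next
    nb <- c()
    for (o in seq_len(nrow(off))) {
      p <- c(i, j, k) + off[o, ]
      if (any(p < 1) || any(p > d)) next
      pl <- lev[p[1], p[2], p[3]]
      if (pl != 0) nb <- c(nb, pl)
    }
    n_i[v] <- n_i[v] + 1L
    if (length(nb)) s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  list(n_i = n_i, s_i = s_i)
}

# A random small discretized ROI for oracle comparisons.
random_levels <- function(dims = c(5, 5, 3), n_levels = 4, p_roi = 0.8) {
  lev <- array(0L, dim = dims)
  inside <- stats::runif(prod(dims)) < p_roi
  lev[inside] <- sample.int(n_levels, sum(inside), replace = TRUE)
  lev
}

as_droi <- function(lev, bin_width = 1) {
  structure(list(levels = lev, n_levels = max(lev), bin_width = bin_width,
                 min_value = 0, spacing = c(1, 1, 1)),
            class = "discretized_roi")
}

# Small volume/mask helpers used across test files.
toy_volume <- function(values, spacing = c(1, 1, 1), modality = "t1w") {
  image_volume(values, spacing, modality)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  roi_mask(array(1L, dim = dims), spacing)
}

small_cohort <- function(n_patients = 6, seed = 42, ...) {
  generate_cohort(cohort_params(n_patients = n_patients, seed = seed, ...))
}
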