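# Shared fixtures and independent oracles. Everything here is deliberately
# plain R, written against the definitions rather than the package's
# computational paths, so tests compare two independent routes.

tiny_grid <- function(n = 16, voxel = 4, type = "box") {
  synthetic_grid(rep(n, 3), voxel, type)
}

# a random experiment with foci at in-mask voxel centres
rand_experiment <- function(grid, id, n_foci, n_range = c(10, 40)) {
  idx <- sample(grid$mask_idx, n_foci)
  mm <- voxel_to_mm(grid, linear_to_voxel_r(grid, idx))
  experiment(id, sample(n_range[1]:n_range[2], 1), mm)
}

rand_dataset <- function(grid, n_exp, max_foci = 8, label = "rand") {
  coordinate_dataset(label, lapply(seq_len(n_exp), function(i)
    rand_experiment(grid, sprintf("exp%02d", i), sample(1:max_foci, 1))))
}

# independent linear-index -> 0-based voxel conversion
linear_to_voxel_r <- function(grid, idx) {
  i0 <- as.integer(idx) - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cbind(i0 %% nx, (i0 %/% nx) %% ny, i0 %/% (nx * ny))
}

# Brute-force MA oracle: one full-grid array per focus built by direct
# offset placement from the kernel stencil, then a voxel-by-voxel max.
oracle_ma <- function(experiment, kernel, grid) {
  st <- kernel_profile(experiment$n_subjects, kernel, grid)
  foci_vox <- mm_to_voxel(grid, experiment$foci)
  per_focus <- lapply(seq_len(nrow(foci_vox)), function(f) {
    arr <- array(0, dim = grid$shape)
    pos <- sweep(st$offsets, 2, foci_vox[f, ], `+`)
    ok <- pos[, 1] >= 0 & pos[, 1] < grid$shape[1] &
      pos[, 2] >= 0 & pos[, 2] < grid$shape[2] &
      pos[, 3] >= 0 & pos[, 3] < grid$shape[3]
    lin <- 1L + pos[ok, 1] + grid$shape[1] *
      (pos[ok, 2] + grid$shape[2] * pos[ok, 3])
    arr[lin] <- st$values[ok]
    arr
  })
  Reduce(pmax, per_focus)
}

# naive union-of-probabilities ALE oracle
oracle_ale <- function(ma_list) {
  arrs <- lapply(ma_list, function(m) if (inherits(m, "ma_map")) m$values else m)
  out <- array(0, dim = dim(arrs[[1]]))
  for (v in seq_along(out)) {
    prod1m <- 1
    for (a in arrs) prod1m <- prod1m * (1 - a[v])
    out[v] <- 1 - prod1m
  }
  out
}

# naive 26-connectivity flood-fill labelling, independent of the C++ path
oracle_label <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  nxt <- 0L
  for (s in which(mask)) {
    if (labels[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    labels[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cc <- arrayInd(cur, dims)
      xr <- max(1, cc[1] - 1):min(dims[1], cc[1] + 1)
      yr <- max(1, cc[2] - 1):min(dims[2], cc[2] + 1)
      zr <- max(1, cc[3] - 1):min(dims[3], cc[3] + 1)
      for (x in xr) for (y in yr) for (z in zr) {
        lin <- x + dims[1] * ((y - 1L) + dims[2] * (z - 1L))
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# enumeration oracles for the voxel-wise comparison metrics
oracle_metrics <- function(a, b) {
  inter <- 0L; uni <- 0L; na <- 0L; nb <- 0L
  for (v in seq_along(a)) {
    if (a[v] && b[v]) inter <- inter + 1L
    if (a[v] || b[v]) uni <- uni + 1L
    if (a[v]) na <- na + 1L
    if (b[v]) nb <- nb + 1L
  }
  list(jaccard = inter / uni, sensitivity = inter / na,
       precision = inter / nb)
}

oracle_cluster_overlap <- function(a, b) {
  la <- oracle_label(a); lb <- oracle_label(b)
  na <- max(la); nb <- max(lb)
  a_over <- sum(vapply(seq_len(na), function(i) any(b[la == i]), logical(1)))
  b_over <- sum(vapply(seq_len(nb), function(i) any(a[lb == i]), logical(1)))
  list(n_cm = na, n_mc = nb, n_cm_overlapping = a_over,
       n_mc_overlapping = b_over,
       cluster_sensitivity = a_over / na, cluster_precision = b_over / nb)
}

oracle_median_nn <- function(from, to) {
  d <- numeric(nrow(from))
  for (i in seq_len(nrow(from))) {
    best <- Inf
    for (j in seq_len(nrow(to))) {
      dist <- sqrt(sum((from[i, ] - to[j, ])^2))
      if (dist < best) best <- dist
    }
    d[i] <- best
  }
  median(d)
}

# does any significant voxel lie within tol mm of a ground-truth centre?
detects_centre <- function(sig, grid, centre, tol = 10) {
  idx <- which(sig)
  if (!length(idx)) return(FALSE)
  mm <- voxel_to_mm(grid, linear_to_voxel_r(grid, idx))
  any(sqrt(colSums((t(mm) - centre)^2)) <= tol)
}

# a minimal contrast_result wrapper, for comparisons against a given map
fake_contrast <- function(sig, z, alpha = 0.001) {
  structure(list(ale_diff = z, p_perm = NULL, z = z, significant = sig,
                 direction = "self", settings = list(alpha = alpha, k = 1L,
                                                     n_perm = 0L)),
            class = "contrast_result")
}
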