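#' Uncorrected ALE analysis of one dataset
#'
#' Computes the ALE map, its analytic null, and the uncorrected p and z
#' maps. Outside the analysis mask, ALE is set to 0, p to 1 and z to NA.
#'
#' @param dataset A [coordinate_dataset].
#' @param kernel A [kernel_model].
#' @param grid A [brain_grid].
#' @param bin_width Null histogram bin width, see [analytic_null()].
#' @return List with `ale`, `p`, `z` (arrays), `null` (an `ale_null`) and
#'   the internal per-experiment maps.
#' @export
ale_analysis <- function(dataset, kernel, grid, bin_width = 1e-4) {
  sc <- ale_scores(dataset, kernel, grid)
  null <- analytic_null(sc$ma, grid, bin_width)
  ale <- sc$ale
  out_of_mask <- !grid$mask
  ale[out_of_mask] <- 0
  pz <- ale_to_p(ale, null)
  pz$p[out_of_mask] <- 1
  pz$z[out_of_mask] <- NA_real_
  list(ale = ale, p = pz$p, z = pz$z, null = null,
       ma = sc$ma, stencils = sc$stencils, foci_vox = sc$foci_vox,
       n_experiments = sc$n_experiments)
}

#' Cluster-level FWE-corrected ALE meta-analysis
#'
#' Runs the full ALE inference chain on one dataset: ALE scores, analytic
#' null, uncorrected p/z, cluster-forming threshold at
#' `p < cluster_forming_p`, then a permutation null of maximum cluster
#' sizes. In each permutation every focus of every experiment is relocated
#' to a uniformly random in-mask voxel (foci counts and sample sizes are
#' held constant), the ALE map is recomputed, thresholded at the identical
#' cluster-forming ALE cutoff, and the maximum 26-connected cluster size is
#' recorded. A real cluster is significant if its size strictly exceeds the
#' empirical `(1 - fwe_p)` percentile order statistic of that null.
#'
#' The cluster-forming ALE cutoff is derived once, from the real dataset's
#' analytic null; relocating foci uniformly within the mask leaves the
#' in-mask MA histograms (and hence the analytic null) unchanged, so the
#' permutated maps are thresholded identically by construction.
#'
#' @param dataset A [coordinate_dataset].
#' @param kernel A [kernel_model].
#' @param grid A [brain_grid].
#' @param cluster_forming_p Uncorrected voxel-wise threshold (default 0.001).
#' @param fwe_p Cluster-level FWE threshold (default 0.05).
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Master seed; per-permutation child seeds are derived
#'   deterministically from it.
#' @param bin_width Null histogram bin width.
#' @return An object of class `ale_result` with per-voxel `ale`, `p`, `z`,
#'   integer `cluster_labels` (0 = background), `significant_cluster_ids`,
#'   `cluster_size_null` (one max size per permutation), the `ale_cutoff`
#'   used, a `cluster_table`, the analytic `null`, and `settings`.
#' @export
cfwe_threshold <- function(dataset, kernel, grid, cluster_forming_p = 0.001,
                           fwe_p = 0.05, n_perm = 10000L, seed = 1L,
                           bin_width = 1e-4) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L)
    stop("n_perm must be >= 100 for a reliable cluster-size quantile")
  an <- ale_analysis(dataset, kernel, grid, bin_width)
  cutoff <- ale_cutoff(an$null, cluster_forming_p)
  supra <- an$ale >= cutoff & grid$mask
  labels <- array(label_components_cpp(supra, grid$shape), dim = grid$shape)
  n_clusters <- max(labels)
  sizes <- if (n_clusters > 0) tabulate(labels[labels > 0], n_clusters)
           else integer(0)

  n_foci <- vapply(an$foci_vox, nrow, integer(1))
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  mask_vox <- linear_to_voxel(grid, grid$mask_idx)
  stencil_list <- lapply(an$stencils, function(s) s[c("offsets", "values")])
  total_foci <- sum(n_foci)
  positions <- matrix(0L, nrow = n_perm, ncol = total_foci)
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    positions[i, ] <- sample.int(nrow(mask_vox), total_foci, replace = TRUE)
  }
  null_sizes <- cfwe_null_sizes_cpp(grid$shape, mask_vox, positions - 1L,
                                    n_foci, stencil_list, cutoff, grid$mask)
  size_cut <- sort(null_sizes)[ceiling((1 - fwe_p) * n_perm)]
  sig_ids <- which(sizes > size_cut)

  cluster_table <- cluster_summary(an$ale, an$z, labels, sizes, sig_ids, grid)
  structure(
    list(ale = an$ale, p = an$p, z = an$z, null = an$null,
         cluster_labels = labels, significant_cluster_ids = sig_ids,
         cluster_size_null = null_sizes, ale_cutoff = cutoff,
         cluster_size_cutoff = size_cut, cluster_table = cluster_table,
         grid = grid,
         settings = list(cluster_forming_p = cluster_forming_p,
                         fwe_p = fwe_p, n_perm = n_perm, seed = seed,
                         bin_width = bin_width,
                         n_experiments = an$n_experiments)),
    class = "ale_result")
}

cluster_summary <- function(ale, z, labels, sizes, sig_ids, grid) {
  if (!length(sizes))
    return(data.frame(id = integer(0), size = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      peak_stat = numeric(0), significant = logical(0)))
  rows <- lapply(seq_along(sizes), function(id) {
    idx <- which(labels == id)
    peak <- idx[which.max(ale[idx])]
    mm <- voxel_to_mm(grid, linear_to_voxel(grid, peak))
    data.frame(id = id, size = sizes[id], peak_x = mm[1], peak_y = mm[2],
               peak_z = mm[3], peak_stat = z[peak],
               significant = id %in% sig_ids)
  })
  do.call(rbind, rows)
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf(
    "<ale_result> %d experiments, %d cluster(s), %d significant (cFWE p < %g)\n",
    x$settings$n_experiments, nrow(x$cluster_table),
    length(x$significant_cluster_ids), x$settings$fwe_p))
  invisible(x)
}

#' Binary significance map of an ALE result
#'
#' @param result An `ale_result`.
#' @return Logical array: voxels in cFWE-significant clusters.
#' @export
significant_map <- function(result) {
  array(result$cluster_labels %in% result$significant_cluster_ids &
          result$cluster_labels > 0, dim = dim(result$cluster_labels))
}

#' Write all volumetric outputs of an ALE result
#'
#' Writes `ale.nii.gz`, `p.nii.gz`, `z.nii.gz`, `clusters.nii.gz` (integer
#' labels), a cluster table TSV and the null histogram JSON into `dir`.
#'
#' @param result An `ale_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ale_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$grid
  z <- result$z
  z[is.na(z)] <- 0
  write_map(result$ale, grid, file.path(dir, "ale.nii.gz"))
  write_map(result$p, grid, file.path(dir, "p.nii.gz"))
  write_map(z, grid, file.path(dir, "z.nii.gz"))
  write_map(result$cluster_labels, grid, file.path(dir, "clusters.nii.gz"))
  utils::write.table(result$cluster_table, file.path(dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  nz <- which(result$null$probabilities > 0)
  jsonlite::write_json(
    list(bin_width = result$null$bin_width,
         bin = nz - 1L, probability = result$null$probabilities[nz]),
    file.path(dir, "null_histogram.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
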