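#' Voxel-wise ALE difference between two datasets
#'
#' Computes the two ALE maps and returns their voxel-wise difference
#' `ALE(A) - ALE(B)`. Swapping the datasets negates the map bit-exactly.
#'
#' @param dataset_a,dataset_b [coordinate_dataset] objects.
#' @param kernel A [kernel_model].
#' @param grid A [brain_grid] shared by both datasets.
#' @return Numeric array of differences in `[-1, 1]`.
#' @export
ale_difference <- function(dataset_a, dataset_b, kernel, grid) {
  ale_scores(dataset_a, kernel, grid)$ale -
    ale_scores(dataset_b, kernel, grid)$ale
}

#' Meta-analytic contrast by pool-shuffle-split permutation
#'
#' Tests, voxel by voxel, whether the observed ALE difference
#' `ALE(A) - ALE(B)` exceeds what is expected if the experiments of the two
#' conditions were exchangeable. For each permutation the pooled experiment
#' list is shuffled and split into pseudo-groups of the original sizes
#' (whole experiments are shuffled, never individual foci, so each
#' experiment's foci count and sample size travel together), and the pseudo
#' ALE difference is recorded. The permutation p-value uses the add-one
#' small-sample correction
#' \deqn{p(v) = (1 + \#\{perm \ge obs\}) / (1 + n_{perm}),}
#' so p is never 0 and z is finite. A voxel is significant when
#' `p_perm < alpha` (i.e. the observed difference beats more than
#' `1 - alpha` of the null), it lies inside the main-effect mask, and it
#' belongs to a 26-connected significant component of at least `k` voxels
#' (extent filtering is applied after masking). The test is one-sided in
#' the direction A > B; call again with the datasets swapped for the
#' reverse contrast.
#'
#' @param dataset_a Condition of interest (A).
#' @param dataset_b Reference condition (B).
#' @param kernel A [kernel_model].
#' @param grid A [brain_grid].
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param alpha Voxel-wise one-sided significance level (default 0.05).
#' @param main_effect_mask Logical array on the grid restricting where
#'   significance may be declared (inclusive masking by the condition of
#'   interest's own main effect), or `NULL` for no masking.
#' @param k Cluster extent threshold in voxels (default 5).
#' @param seed Master seed for the permutation stream.
#' @return An object of class `contrast_result` with `ale_diff`, `p_perm`,
#'   `z`, logical `significant`, `direction`, and `settings`.
#' @export
contrast_permutation_test <- function(dataset_a, dataset_b, kernel, grid,
                                      n_perm = 10000L, alpha = 0.05,
                                      main_effect_mask = NULL, k = 5L,
                                      seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  nA <- length(dataset_a$experiments)
  nB <- length(dataset_b$experiments)
  if (nA + nB < 4L)
    stop("too few experiments for a permutation null (|A| + |B| < 4)")
  if (!is.null(main_effect_mask) &&
      !identical(as.integer(dim(main_effect_mask)), grid$shape))
    stop("main_effect_mask must be on the same grid")

  pooled <- c(dataset_a$experiments, dataset_b$experiments)
  stencils <- dataset_stencils(
    structure(list(label = "pooled", experiments = pooled),
              class = "coordinate_dataset"), kernel, grid)
  V <- length(grid$mask_idx)
  Q <- matrix(1, nrow = V, ncol = length(pooled))
  for (e in seq_along(pooled)) {
    ma <- ma_map_cpp(grid$shape, foci_voxels(pooled[[e]], grid),
                     stencils[[e]]$offsets, stencils[[e]]$values)
    Q[, e] <- 1 - ma[grid$mask_idx]
  }
  idx_a <- seq_len(nA) - 1L
  idx_b <- nA + seq_len(nB) - 1L
  obs <- group_diff_cpp(Q, idx_a, idx_b)

  set.seed(seed)
  splits <- t(vapply(seq_len(n_perm),
                     function(i) sort(sample.int(nA + nB, nA)) - 1L,
                     integer(nA)))
  counts <- contrast_perm_counts_cpp(Q, splits, obs)
  p_vec <- (1 + counts) / (1 + n_perm)
  p_eff <- pmin(pmax(p_vec, 1 / (n_perm + 1)), n_perm / (n_perm + 1))
  z_vec <- stats::qnorm(p_eff, lower.tail = FALSE)

  ale_diff <- array(0, dim = grid$shape)
  ale_diff[grid$mask_idx] <- obs
  p_perm <- array(1, dim = grid$shape)
  p_perm[grid$mask_idx] <- p_vec
  z <- array(NA_real_, dim = grid$shape)
  z[grid$mask_idx] <- z_vec

  sig <- p_perm < alpha & grid$mask
  if (!is.null(main_effect_mask)) sig <- sig & (main_effect_mask > 0)
  labels <- array(label_components_cpp(sig, grid$shape), dim = grid$shape)
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0], max(labels))
    keep <- which(sizes >= k)
    sig <- array(labels %in% keep & labels > 0, dim = grid$shape)
  }

  structure(
    list(ale_diff = ale_diff, p_perm = p_perm, z = z, significant = sig,
         direction = paste0(dataset_a$label, " > ", dataset_b$label),
         settings = list(n_perm = n_perm, alpha = alpha, k = k, seed = seed,
                         n_a = nA, n_b = nB,
                         masked = !is.null(main_effect_mask))),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s: %d significant voxel(s) (alpha = %g, k = %d)\n",
              x$direction, sum(x$significant), x$settings$alpha, x$settings$k))
  invisible(x)
}

#' Full meta-analytic contrast between two conditions
#'
#' Convenience composition: computes the two main-effect ALE analyses,
#' derives the inclusive main-effect mask for the condition of interest
#' (A), and runs the pool-shuffle-split permutation contrast A > B. By
#' default the mask is A's uncorrected `p < mask_p` map; with
#' `mask_type = "cfwe"` the cluster-level corrected map of A is used
#' instead (slower: runs the full cFWE permutation chain on A).
#'
#' @param dataset_a Condition of interest (A > baseline experiments).
#' @param dataset_b Reference condition (B > baseline experiments).
#' @param kernel A [kernel_model].
#' @param grid A [brain_grid].
#' @param n_perm Permutations for the contrast null (and for cFWE when
#'   `mask_type = "cfwe"`).
#' @param alpha Voxel-wise significance level for the contrast.
#' @param k Cluster extent threshold.
#' @param mask_type `"uncorrected"` (default) or `"cfwe"`.
#' @param mask_p Uncorrected threshold defining the main-effect mask.
#' @param seed Master seed; independent child seeds are derived for the
#'   contrast permutations and (if used) the cFWE permutations.
#' @param bin_width Null histogram bin width.
#' @return An object of class `mc_result`: the `contrast`
#'   ([contrast_permutation_test()] result), the two main-effect analyses
#'   `main_a`, `main_b`, the `main_effect_mask` used, and `settings`.
#' @export
run_mc <- function(dataset_a, dataset_b, kernel, grid, n_perm = 10000L,
                   alpha = 0.05, k = 5L, mask_type = c("uncorrected", "cfwe"),
                   mask_p = 0.001, seed = 1L, bin_width = 1e-4) {
  mask_type <- match.arg(mask_type)
  if (mask_type == "cfwe") {
    main_a <- cfwe_threshold(dataset_a, kernel, grid,
                             cluster_forming_p = mask_p, n_perm = n_perm,
                             seed = child_seed(seed, 11L),
                             bin_width = bin_width)
    mask <- significant_map(main_a)
  } else {
    main_a <- ale_analysis(dataset_a, kernel, grid, bin_width)
    mask <- main_a$p < mask_p & grid$mask
  }
  main_b <- ale_analysis(dataset_b, kernel, grid, bin_width)
  contrast <- contrast_permutation_test(
    dataset_a, dataset_b, kernel, grid, n_perm = n_perm, alpha = alpha,
    main_effect_mask = mask, k = k, seed = child_seed(seed, 12L))
  structure(
    list(contrast = contrast, main_a = main_a, main_b = main_b,
         main_effect_mask = mask, grid = grid,
         settings = list(n_perm = n_perm, alpha = alpha, k = k,
                         mask_type = mask_type, mask_p = mask_p,
                         seed = seed)),
    class = "mc_result")
}

#' Write all volumetric outputs of a meta-analytic contrast
#'
#' Writes `diff.nii.gz`, `p_perm.nii.gz`, `z.nii.gz`, `significant.nii.gz`
#' and a JSON echo of the settings (seed, n_perm, alpha, k, mask
#' provenance) into `dir`.
#'
#' @param mc An `mc_result` or `contrast_result`.
#' @param grid A [brain_grid] (taken from `mc` if present).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mc_result <- function(mc, dir, grid = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contrast <- if (inherits(mc, "mc_result")) mc$contrast else mc
  if (is.null(grid)) grid <- mc$grid
  z <- contrast$z
  z[is.na(z)] <- 0
  write_map(contrast$ale_diff, grid, file.path(dir, "diff.nii.gz"))
  write_map(contrast$p_perm, grid, file.path(dir, "p_perm.nii.gz"))
  write_map(z, grid, file.path(dir, "z.nii.gz"))
  write_map(contrast$significant + 0, grid, file.path(dir, "significant.nii.gz"))
  settings <- contrast$settings
  if (inherits(mc, "mc_result"))
    settings <- c(settings, mc$settings[c("mask_type", "mask_p")])
  settings$direction <- contrast$direction
  jsonlite::write_json(settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
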