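#' Modeled activation map of one experiment
#'
#' Stamps every focus's kernel stencil onto the grid; where stencils of
#' nearby foci overlap, each voxel receives only the largest per-focus
#' probability (the non-additive max rule), so clusters of close-by reported
#' peaks do not inflate the map.
#'
#' @param experiment An [experiment].
#' @param kernel A [kernel_model].
#' @param grid A [brain_grid].
#' @return An object of class `ma_map`: list with `values` (array on the
#'   grid, in `[0, 1]`) and `study_id`.
#' @export
build_ma_map <- function(experiment, kernel, grid) {
  stencil <- kernel_profile(experiment$n_subjects, kernel, grid)
  vox <- foci_voxels(experiment, grid)
  vals <- ma_map_cpp(grid$shape, vox, stencil$offsets, stencil$values)
  structure(list(values = array(vals, dim = grid$shape),
                 study_id = experiment$study_id),
            class = "ma_map")
}

# foci of one experiment as 0-based voxel indices (nearest-voxel rounding);
# foci outside the mask are kept (their kernel may still overlap the mask)
# but logged
foci_voxels <- function(experiment, grid) {
  vox <- mm_to_voxel(grid, experiment$foci)
  lin <- voxel_to_linear(grid, vox)
  outside <- is.na(lin) | !grid$mask[ifelse(is.na(lin), 1L, lin)]
  if (any(outside))
    message(sum(outside), " focus/foci of '", experiment$study_id,
            "' fall outside the mask (kept)")
  vox
}

#' Voxel-wise ALE scores from modeled activation maps
#'
#' Combines the per-experiment maps by the voxel-wise union of
#' probabilities: \deqn{ALE(v) = 1 - \prod_i (1 - MA_i(v)).}
#' ALE never decreases when an experiment is added.
#'
#' @param ma_maps Non-empty list of [build_ma_map()] results (or plain
#'   arrays) on a common grid.
#' @return Numeric array of ALE scores in `[0, 1]`.
#' @export
compute_ale <- function(ma_maps) {
  if (length(ma_maps) == 0L) stop("`ma_maps` must contain at least one map")
  arrs <- lapply(ma_maps, function(m) if (inherits(m, "ma_map")) m$values else m)
  dims <- lapply(arrs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all MA maps must share one grid")
  if (length(arrs) == 1L) return(arrs[[1]])  # union of one map is the map
  acc <- array(1, dim = dims[[1]])
  for (a in arrs) acc <- acc * (1 - a)
  1 - acc
}

# Canonical dataset-level ALE: experiments are processed in study_id order so
# that the result (and everything downstream: null, p, z) is bit-identical
# under permutation of the input experiment list.
ale_scores <- function(dataset, kernel, grid) {
  ord <- order(vapply(dataset$experiments, `[[`, character(1), "study_id"),
               method = "radix")
  exps <- dataset$experiments[ord]
  stencils <- dataset_stencils(coordinate_dataset(dataset$label, exps),
                               kernel, grid)
  foci_vox <- lapply(exps, foci_voxels, grid = grid)
  ma <- lapply(seq_along(exps), function(i)
    ma_map_cpp(grid$shape, foci_vox[[i]], stencils[[i]]$offsets,
               stencils[[i]]$values))
  acc <- rep(1, prod(grid$shape))
  for (m in ma) acc <- acc * (1 - m)
  list(ale = array(1 - acc, dim = grid$shape),
       ma = ma, stencils = stencils, foci_vox = foci_vox,
       n_experiments = length(exps))
}
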