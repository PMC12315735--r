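#' Ground-truth convergence centre
#'
#' One location where synthetic experiments may converge, with separate hit
#' rates for the three condition types: `hit_rate_a` / `hit_rate_b` apply
#' to the main-effect datasets (A > baseline, B > baseline), and
#' `hit_rate_diff` to the difference-contrast dataset (A > B) that feeds
#' the experiment-level contrast meta-analysis.
#'
#' @param centre_mm Length-3 mm coordinate; must fall inside the analysis
#'   mask of the grid used for generation.
#' @param hit_rate_a,hit_rate_b,hit_rate_diff Probabilities in `[0, 1]`
#'   that an experiment of the respective condition contributes a focus
#'   near this centre.
#' @param jitter_sd_mm Isotropic Gaussian jitter (sd, mm) of contributed
#'   foci around the centre.
#' @return An object of class `ground_truth_centre`.
#' @export
ground_truth_centre <- function(centre_mm, hit_rate_a = 0, hit_rate_b = 0,
                                hit_rate_diff = 0, jitter_sd_mm = 5) {
  stopifnot(length(centre_mm) == 3, all(is.finite(centre_mm)),
            jitter_sd_mm > 0)
  rates <- c(hit_rate_a, hit_rate_b, hit_rate_diff)
  if (any(rates < 0 | rates > 1)) stop("hit rates must be in [0, 1]")
  structure(list(centre_mm = as.numeric(centre_mm), hit_rate_a = hit_rate_a,
                 hit_rate_b = hit_rate_b, hit_rate_diff = hit_rate_diff,
                 jitter_sd_mm = jitter_sd_mm),
            class = "ground_truth_centre")
}

#' Synthetic scenario specification
#'
#' Describes a full synthetic study collection mirroring the structure of
#' a real coordinate-based meta-analytic evaluation: three condition
#' datasets (A > baseline, B > baseline and the difference contrast
#' A > B), each a list of experiments with variable sample size,
#' ground-truth convergence centres shared or differential between
#' conditions, spatial jitter around the centres, and uniformly scattered
#' noise foci inside the mask.
#'
#' @param centres List of [ground_truth_centre] objects (may be empty for
#'   a pure-noise scenario).
#' @param n_experiments_a,n_experiments_b,n_experiments_diff Experiments
#'   per condition dataset.
#' @param n_subjects_range Integer interval for per-experiment sample
#'   sizes (drawn uniformly).
#' @param noise_foci_range Integer interval for per-experiment uniform
#'   noise foci counts.
#' @param seed Scenario master seed. Seeds propagate hierarchically
#'   (scenario -> condition -> experiment), so adding experiments does not
#'   perturb earlier ones.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(centres = list(), n_experiments_a = 25L,
                          n_experiments_b = 25L, n_experiments_diff = 25L,
                          n_subjects_range = c(10L, 40L),
                          noise_foci_range = c(2L, 10L), seed = 1L) {
  counts <- c(n_experiments_a, n_experiments_b, n_experiments_diff)
  if (any(counts < 1L)) stop("all experiment counts must be >= 1")
  if (length(n_subjects_range) != 2L || n_subjects_range[1] > n_subjects_range[2]
      || n_subjects_range[1] < 1L)
    stop("`n_subjects_range` must be a non-empty positive interval")
  if (length(noise_foci_range) != 2L || noise_foci_range[1] > noise_foci_range[2]
      || noise_foci_range[1] < 0L)
    stop("`noise_foci_range` must be a non-empty non-negative interval")
  if (length(centres) && !all(vapply(centres, inherits, logical(1),
                                     "ground_truth_centre")))
    stop("`centres` must be ground_truth_centre objects")
  structure(list(centres = centres,
                 n_experiments_a = as.integer(n_experiments_a),
                 n_experiments_b = as.integer(n_experiments_b),
                 n_experiments_diff = as.integer(n_experiments_diff),
                 n_subjects_range = as.integer(n_subjects_range),
                 noise_foci_range = as.integer(noise_foci_range),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

cond_index <- function(condition) {
  match(condition, c("A", "B", "diff"))
}

#' Generate one synthetic condition dataset
#'
#' For each experiment, the sample size is drawn uniformly from the
#' scenario's range; each ground-truth centre contributes, with the
#' condition's hit rate, one focus at `centre + N(0, jitter_sd^2 I)`,
#' redrawn (not projected) until it lands inside the mask to avoid
#' boundary pile-up; noise foci are placed uniformly over in-mask voxels.
#' The result is fully determined by `(spec$seed, condition, experiment
#' index)`.
#'
#' @param spec A [scenario_spec].
#' @param condition `"A"`, `"B"` or `"diff"`.
#' @param grid A [brain_grid]; all centres must lie inside its mask.
#' @return A [coordinate_dataset].
#' @export
generate_dataset <- function(spec, condition = c("A", "B", "diff"), grid) {
  condition <- match.arg(condition)
  ci <- cond_index(condition)
  rate_field <- c("hit_rate_a", "hit_rate_b", "hit_rate_diff")[ci]
  rates <- vapply(spec$centres, `[[`, numeric(1), rate_field)
  if ((!length(rates) || all(rates == 0)) && spec$noise_foci_range[2] == 0L)
    stop("scenario would generate empty experiments: all hit rates zero ",
         "and no noise foci")
  for (ct in spec$centres) {
    lin <- voxel_to_linear(grid, mm_to_voxel(grid, ct$centre_mm))
    if (is.na(lin) || !grid$mask[lin])
      stop("ground-truth centre outside the mask: ",
           paste(ct$centre_mm, collapse = ", "))
  }
  n_exp <- spec[[c("n_experiments_a", "n_experiments_b",
                   "n_experiments_diff")[ci]]]
  mask_mm <- voxel_to_mm(grid, linear_to_voxel(grid, grid$mask_idx))
  draw_one <- function(lo, hi) {       # safe even when lo == hi
    v <- lo:hi
    v[sample.int(length(v), 1L)]
  }
  exps <- lapply(seq_len(n_exp), function(i) {
    set.seed(child_seed(spec$seed, ci * 100000L + i))
    n_subj <- draw_one(spec$n_subjects_range[1], spec$n_subjects_range[2])
    foci <- matrix(numeric(0), ncol = 3)
    for (ct in spec$centres) {
      if (stats::runif(1) >= ct[[rate_field]]) next
      repeat {
        f <- ct$centre_mm + stats::rnorm(3, sd = ct$jitter_sd_mm)
        lin <- voxel_to_linear(grid, mm_to_voxel(grid, f))
        if (!is.na(lin) && grid$mask[lin]) break
      }
      foci <- rbind(foci, f)
    }
    n_noise <- draw_one(spec$noise_foci_range[1], spec$noise_foci_range[2])
    if (n_noise > 0) {
      pick <- sample.int(nrow(mask_mm), n_noise, replace = FALSE)
      foci <- rbind(foci, mask_mm[pick, , drop = FALSE])
    }
    experiment(sprintf("synth_%s_%03d", condition, i), n_subj, foci)
  })
  coordinate_dataset(paste0("synthetic ", condition), exps)
}

#' Built-in scenario presets
#'
#' Three regimes covering the qualitatively distinct behaviours of the two
#' contrast approaches:
#' \describe{
#'   \item{differential_only}{One centre hit by 60\% of condition-A and of
#'     difference-contrast experiments, never by condition B: both
#'     approaches should recover it.}
#'   \item{shared_activation}{Both conditions converge at the same centre
#'     with equal hit rates while the difference-contrast experiments also
#'     converge there: the experiment-level meta-analysis (CM) sees the
#'     differences, but a contrast between the two equally convergent main
#'     effects (MC) has nothing to pick up — differences in activation
#'     strength are invisible to a contrast of convergence maps.}
#'   \item{null}{No centres: pure uniform noise, all experiments
#'     exchangeable between conditions.}
#' }
#' Defaults (hit rate 0.6, jitter 5 mm, 2-10 noise foci, sample sizes
#' 10-40, 30/30/30 experiments, 25 each for the null preset) are of the
#' order of magnitude typical of task-fMRI meta-analytic datasets; they
#' are configuration, not claims about any particular literature.
#'
#' @param name Preset name.
#' @param seed Scenario seed.
#' @param grid A [brain_grid] used to place the centre (defaults to
#'   [synthetic_grid()] geometry: centre at the mm origin offset well
#'   inside the mask).
#' @return A [scenario_spec].
#' @export
preset <- function(name = c("differential_only", "shared_activation", "null"),
                   seed = 1L, grid = NULL) {
  name <- match.arg(name)
  centre <- c(0, 16, 8)
  switch(name,
    differential_only = scenario_spec(
      centres = list(ground_truth_centre(centre, hit_rate_a = 0.6,
                                         hit_rate_b = 0,
                                         hit_rate_diff = 0.6)),
      n_experiments_a = 30L, n_experiments_b = 30L, n_experiments_diff = 30L,
      seed = seed),
    shared_activation = scenario_spec(
      centres = list(ground_truth_centre(centre, hit_rate_a = 0.6,
                                         hit_rate_b = 0.6,
                                         hit_rate_diff = 0.6)),
      n_experiments_a = 30L, n_experiments_b = 30L, n_experiments_diff = 30L,
      seed = seed),
    null = scenario_spec(centres = list(), n_experiments_a = 25L,
                         n_experiments_b = 25L, n_experiments_diff = 25L,
                         seed = seed))
}

#' Write a scenario's ground truth as JSON
#'
#' Serializes centres, hit rates, counts and seeds so that recovery can be
#' scored against the generating truth.
#'
#' @param spec A [scenario_spec].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scenario_truth <- function(spec, path) {
  jsonlite::write_json(
    list(centres = lapply(spec$centres, unclass),
         n_experiments = list(A = spec$n_experiments_a,
                              B = spec$n_experiments_b,
                              diff = spec$n_experiments_diff),
         n_subjects_range = spec$n_subjects_range,
         noise_foci_range = spec$noise_foci_range,
         seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
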