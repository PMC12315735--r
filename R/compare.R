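#' Voxel-wise Jaccard coefficient of two binary maps
#'
#' `|a intersect b| / |a union b|` over significant voxels. Undefined (NaN,
#' with a warning) when both maps are empty.
#'
#' @param a,b Logical arrays of identical shape (binarized significance
#'   maps).
#' @return Numeric scalar in `[0, 1]`, or NaN.
#' @export
jaccard <- function(a, b) {
  check_same_shape(a, b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("jaccard undefined: both maps empty")
    return(NaN)
  }
  sum(a & b) / uni
}

#' Voxel-wise sensitivity of MC with respect to CM
#'
#' Proportion of significant CM voxels also significant in MC:
#' `|cm intersect mc| / |cm|`. Reflects how well the meta-analytic contrast
#' recovers the network of the experiment-level contrast meta-analysis.
#'
#' @param cm,mc Logical arrays of identical shape.
#' @return Numeric scalar in `[0, 1]`, or NaN when `cm` is empty.
#' @export
voxel_sensitivity <- function(cm, mc) {
  check_same_shape(cm, mc)
  denom <- sum(cm)
  if (denom == 0) {
    warning("sensitivity undefined: CM map empty")
    return(NaN)
  }
  sum(cm & mc) / denom
}

#' Voxel-wise precision of MC with respect to CM
#'
#' Proportion of significant MC voxels that lie within the CM network:
#' `|cm intersect mc| / |mc|`.
#'
#' @param cm,mc Logical arrays of identical shape.
#' @return Numeric scalar in `[0, 1]`, or NaN when `mc` is empty.
#' @export
voxel_precision <- function(cm, mc) {
  check_same_shape(cm, mc)
  denom <- sum(mc)
  if (denom == 0) {
    warning("precision undefined: MC map empty")
    return(NaN)
  }
  sum(cm & mc) / denom
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("maps must share one grid shape")
  invisible(TRUE)
}

#' Cluster-wise overlap between two binary maps
#'
#' Clusters are 26-connected components (configurable to 6). A cluster
#' counts as overlapping if it shares at least one voxel with the other
#' map. Cluster sensitivity is the fraction of CM clusters overlapping MC;
#' cluster precision the fraction of MC clusters overlapping CM. A side
#' with zero clusters yields NaN for its ratio, with a warning.
#'
#' @param cm,mc Logical arrays of identical shape.
#' @param connectivity 26 (default) or 6.
#' @return List with `n_cm`, `n_mc`, `n_cm_overlapping`, `n_mc_overlapping`,
#'   `cluster_sensitivity`, `cluster_precision`.
#' @export
cluster_overlap <- function(cm, mc, connectivity = 26L) {
  check_same_shape(cm, mc)
  lab_cm <- label_clusters(cm, connectivity)
  lab_mc <- label_clusters(mc, connectivity)
  n_cm <- max(lab_cm); n_mc <- max(lab_mc)
  cm_over <- length(unique(lab_cm[lab_cm > 0 & mc]))
  mc_over <- length(unique(lab_mc[lab_mc > 0 & cm]))
  sens <- if (n_cm == 0) {
    warning("cluster sensitivity undefined: CM has no clusters"); NaN
  } else cm_over / n_cm
  prec <- if (n_mc == 0) {
    warning("cluster precision undefined: MC has no clusters"); NaN
  } else mc_over / n_mc
  list(n_cm = n_cm, n_mc = n_mc, n_cm_overlapping = cm_over,
       n_mc_overlapping = mc_over, cluster_sensitivity = sens,
       cluster_precision = prec)
}

#' Label connected components of a binary volume
#'
#' @param mask Logical array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of component labels (0 = background).
#' @export
label_clusters <- function(mask, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  dims <- dim(mask)
  if (length(dims) != 3L) stop("`mask` must be a 3-D array")
  if (connectivity == 26L)
    return(array(label_components_cpp(mask, dims), dim = dims))
  if (connectivity != 6L) stop("connectivity must be 6 or 26")
  label_components_6(mask, dims)
}

# 6-connectivity labelling (face neighbours only), plain R
label_components_6 <- function(mask, dims) {
  labels <- array(0L, dim = dims)
  nxt <- 0L
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
              c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  todo <- which(mask)
  for (s in todo) {
    if (labels[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    labels[s] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, dims)
      for (j in seq_len(6)) {
        v <- cc + nb[j, ]
        if (any(v < 1L) || any(v > dims)) next
        lin <- v[1] + dims[1] * ((v[2] - 1L) + dims[2] * (v[3] - 1L))
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

#' Extract local-maximum peaks from a statistic map
#'
#' Candidate voxels are supra-threshold voxels whose value is at least that
#' of all 26 neighbours. Peaks are then selected greedily in descending
#' statistic order, discarding any candidate within `min_distance_mm` (mm,
#' Euclidean) of an already accepted peak; ties in value are broken by the
#' lexicographic (linear) voxel index. An empty result is not an error.
#'
#' @param stat_map Numeric array on the grid; NA values (e.g. out-of-mask)
#'   are ignored.
#' @param grid A [brain_grid].
#' @param threshold Only voxels with value >= threshold are candidates.
#' @param min_distance_mm Minimum separation between accepted peaks
#'   (default 8 mm, the SPM default).
#' @return An object of class `peak_set`: data.frame `peaks` with columns
#'   `x`, `y`, `z` (mm), `value`, plus `min_separation_mm`.
#' @export
extract_peaks <- function(stat_map, grid, threshold,
                          min_distance_mm = 8) {
  stopifnot(is.finite(threshold), min_distance_mm > 0)
  vals <- stat_map
  vals[is.na(vals)] <- -Inf
  cand <- which(vals >= threshold)
  if (length(cand)) {
    dims <- grid$shape
    keep <- vapply(cand, function(lin) {
      v <- linear_to_voxel(grid, lin)
      x0 <- max(v[1] - 1L, 0L):min(v[1] + 1L, dims[1] - 1L)
      y0 <- max(v[2] - 1L, 0L):min(v[2] + 1L, dims[2] - 1L)
      z0 <- max(v[3] - 1L, 0L):min(v[3] + 1L, dims[3] - 1L)
      vals[lin] >= max(vals[x0 + 1L, y0 + 1L, z0 + 1L])
    }, logical(1))
    cand <- cand[keep]
  }
  peaks <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0))
  if (length(cand)) {
    ord <- order(-vals[cand], cand)
    cand <- cand[ord]
    mm <- voxel_to_mm(grid, linear_to_voxel(grid, cand))
    accepted <- integer(0)
    for (i in seq_along(cand)) {
      if (length(accepted)) {
        d <- sqrt(colSums((t(mm[accepted, , drop = FALSE]) - mm[i, ])^2))
        if (any(d < min_distance_mm)) next
      }
      accepted <- c(accepted, i)
    }
    peaks <- data.frame(x = mm[accepted, 1], y = mm[accepted, 2],
                        z = mm[accepted, 3], value = vals[cand[accepted]])
  }
  structure(list(peaks = peaks, min_separation_mm = min_distance_mm),
            class = "peak_set")
}

#' Median nearest-peak distance between two peak sets
#'
#' For each peak in `from_set`, the Euclidean mm distance to the nearest
#' peak of `to_set`; returns the median (midpoint convention for even
#' counts). Directional: compute both directions separately.
#'
#' @param from_set,to_set [extract_peaks()] results (non-empty).
#' @return Median distance in mm, or NaN with a warning if either set is
#'   empty.
#' @export
peak_distances <- function(from_set, to_set) {
  from <- as.matrix(from_set$peaks[, c("x", "y", "z")])
  to <- as.matrix(to_set$peaks[, c("x", "y", "z")])
  if (nrow(from) == 0 || nrow(to) == 0) {
    warning("peak distance undefined: empty peak set")
    return(NaN)
  }
  nn <- vapply(seq_len(nrow(from)), function(i)
    min(sqrt(colSums((t(to) - from[i, ])^2))), numeric(1))
  stats::median(nn)
}

#' Full comparison report between CM and MC results
#'
#' Assembles the voxel-wise (Jaccard, sensitivity, precision),
#' cluster-wise (overlap counts and ratios) and peak-wise (median
#' bidirectional nearest-peak distances) similarity metrics between a
#' cluster-corrected ALE result (CM) and a meta-analytic contrast result
#' (MC). Comparison operates on the thresholded significance maps — what a
#' meta-analytic study would report — never on unthresholded maps. Peaks
#' are extracted from each side's uncorrected thresholded z map: the CM z
#' map at its cluster-forming criterion, the MC z map at its voxel-wise
#' alpha (both configurable). Undefined ratios are reported as NaN with a
#' machine-readable reason code, never silently as 0.
#'
#' @param cm_result An `ale_result` (CM side).
#' @param mc_result An `mc_result` or `contrast_result` (MC side).
#' @param grid A [brain_grid] (defaults to the CM result's grid).
#' @param min_peak_distance_mm Minimum peak separation (default 8 mm).
#' @param cm_peak_p,mc_peak_p Uncorrected p thresholds converted to z
#'   cutoffs for peak extraction (defaults: the CM cluster-forming p and
#'   the MC alpha).
#' @param connectivity Cluster connectivity (26 or 6).
#' @return An object of class `comparison_report`.
#' @export
compare_maps <- function(cm_result, mc_result, grid = NULL,
                         min_peak_distance_mm = 8, cm_peak_p = NULL,
                         mc_peak_p = NULL, connectivity = 26L) {
  if (is.null(grid)) grid <- cm_result$grid
  contrast <- if (inherits(mc_result, "mc_result")) mc_result$contrast
              else mc_result
  cm_bin <- if (inherits(cm_result, "ale_result")) significant_map(cm_result)
            else cm_result
  mc_bin <- contrast$significant
  check_same_shape(cm_bin, mc_bin)

  reasons <- character(0)
  metric <- function(expr, code) {
    withCallingHandlers(expr, warning = function(w) {
      reasons[[code]] <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  }
  jac <- metric(jaccard(cm_bin, mc_bin), "jaccard")
  sens <- metric(voxel_sensitivity(cm_bin, mc_bin), "voxel_sensitivity")
  prec <- metric(voxel_precision(cm_bin, mc_bin), "voxel_precision")
  cl <- metric(cluster_overlap(cm_bin, mc_bin, connectivity),
               "cluster_overlap")

  if (is.null(cm_peak_p))
    cm_peak_p <- if (inherits(cm_result, "ale_result"))
      cm_result$settings$cluster_forming_p else 0.001
  if (is.null(mc_peak_p)) mc_peak_p <- contrast$settings$alpha
  cm_z_cut <- stats::qnorm(cm_peak_p, lower.tail = FALSE)
  mc_z_cut <- stats::qnorm(mc_peak_p, lower.tail = FALSE)
  cm_z <- if (inherits(cm_result, "ale_result")) cm_result$z else NULL
  cm_peaks <- if (!is.null(cm_z))
    extract_peaks(cm_z, grid, cm_z_cut, min_peak_distance_mm)
  else structure(list(peaks = data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0), value = numeric(0)),
                      min_separation_mm = min_peak_distance_mm),
                 class = "peak_set")
  mc_peaks <- extract_peaks(contrast$z, grid, mc_z_cut, min_peak_distance_mm)
  d_cm_mc <- metric(peak_distances(cm_peaks, mc_peaks), "dist_cm_to_mc")
  d_mc_cm <- metric(peak_distances(mc_peaks, cm_peaks), "dist_mc_to_cm")

  structure(
    list(jaccard = jac, voxel_sensitivity = sens, voxel_precision = prec,
         n_voxels_cm = sum(cm_bin), n_voxels_mc = sum(mc_bin),
         n_voxels_overlap = sum(cm_bin & mc_bin),
         n_clusters_cm = cl$n_cm, n_clusters_mc = cl$n_mc,
         n_cm_overlapping = cl$n_cm_overlapping,
         n_mc_overlapping = cl$n_mc_overlapping,
         cluster_sensitivity = cl$cluster_sensitivity,
         cluster_precision = cl$cluster_precision,
         median_dist_cm_to_mc_mm = d_cm_mc,
         median_dist_mc_to_cm_mm = d_mc_cm,
         cm_peaks = cm_peaks$peaks, mc_peaks = mc_peaks$peaks,
         direction_note = paste(
           "sensitivity and dist_cm_to_mc read CM -> MC;",
           "precision and dist_mc_to_cm read MC -> CM"),
         undefined_reasons = as.list(reasons)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  voxels: CM %d, MC %d, overlap %d | jaccard %.3f, sens %.3f, prec %.3f\n",
              x$n_voxels_cm, x$n_voxels_mc, x$n_voxels_overlap,
              x$jaccard, x$voxel_sensitivity, x$voxel_precision))
  cat(sprintf("  clusters: CM %d, MC %d | sens %.3f, prec %.3f\n",
              x$n_clusters_cm, x$n_clusters_mc,
              x$cluster_sensitivity, x$cluster_precision))
  cat(sprintf("  median peak dist: CM->MC %.1f mm, MC->CM %.1f mm\n",
              x$median_dist_cm_to_mc_mm, x$median_dist_mc_to_cm_mm))
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes the full report as JSON and the two peak tables as TSV files
#' (`cm_peaks.tsv`, `mc_peaks.tsv`) with columns x, y, z, value, map.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalar_fields <- setdiff(names(report), c("cm_peaks", "mc_peaks"))
  jsonlite::write_json(report[scalar_fields],
                       file.path(dir, "comparison_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "string")
  for (side in c("cm", "mc")) {
    tab <- report[[paste0(side, "_peaks")]]
    tab$map <- toupper(side)
    utils::write.table(tab, file.path(dir, paste0(side, "_peaks.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
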