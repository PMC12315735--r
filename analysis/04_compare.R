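#!/usr/bin/env Rscript

# Step 4 — compare the CM and MC result maps.
#
# Reads the thresholded maps written by steps 2 and 3 and quantifies their
# similarity at voxel level (Jaccard, sensitivity, precision), cluster
# level (overlap counts and ratios) and peak level (median bidirectional
# nearest-peak distances on the uncorrected thresholded z maps).

suppressMessages(library(alecontrast))

grid <- load_grid(file.path("results", "data", "mask.nii.gz"))
read_vol <- function(path) as.array(RNifti::readNifti(path))

rows <- list()
for (name in c("differential_only", "shared_activation", "null")) {
  cm_dir <- file.path("results", "cm", name)
  mc_dir <- file.path("results", "mc", name)

  clusters <- read_vol(file.path(cm_dir, "clusters.nii.gz"))
  tab <- read.delim(file.path(cm_dir, "clusters.tsv"))
  sig_ids <- tab$id[tab$significant]
  cm_bin <- array(clusters %in% sig_ids & clusters > 0, dim = grid$shape)
  mc_bin <- read_vol(file.path(mc_dir, "significant.nii.gz")) > 0

  vox <- suppressWarnings(list(
    jaccard = jaccard(cm_bin, mc_bin),
    sensitivity = voxel_sensitivity(cm_bin, mc_bin),
    precision = voxel_precision(cm_bin, mc_bin)))
  cl <- suppressWarnings(cluster_overlap(cm_bin, mc_bin))

  cm_z <- read_vol(file.path(cm_dir, "z.nii.gz"))
  mc_z <- read_vol(file.path(mc_dir, "z.nii.gz"))
  cm_peaks <- extract_peaks(cm_z, grid, qnorm(0.999))
  mc_peaks <- extract_peaks(mc_z, grid, qnorm(0.95))
  d_cm_mc <- suppressWarnings(peak_distances(cm_peaks, mc_peaks))
  d_mc_cm <- suppressWarnings(peak_distances(mc_peaks, cm_peaks))

  rows[[name]] <- data.frame(
    scenario = name, n_voxels_cm = sum(cm_bin), n_voxels_mc = sum(mc_bin),
    jaccard = vox$jaccard, voxel_sensitivity = vox$sensitivity,
    voxel_precision = vox$precision, n_clusters_cm = cl$n_cm,
    n_clusters_mc = cl$n_mc, cluster_sensitivity = cl$cluster_sensitivity,
    cluster_precision = cl$cluster_precision,
    median_dist_cm_to_mc_mm = d_cm_mc, median_dist_mc_to_cm_mm = d_mc_cm)
  cat(sprintf(
    "%-18s: CM %3d vx / MC %3d vx, jaccard %.3f, cluster sens %.2f, prec %.2f\n",
    name, sum(cm_bin), sum(mc_bin), vox$jaccard,
    cl$cluster_sensitivity, cl$cluster_precision))
}

summary <- do.call(rbind, rows)
out <- file.path("results", "comparison_summary.tsv")
write.table(summary, out, sep = "\t", row.names = FALSE, quote = FALSE)
cat("done: summary written to", out, "\n")
cat("\nReading guide: in the differential-only scenario both approaches\n")
cat("recover the centre; in the shared-activation scenario CM keeps it but\n")
cat("MC loses it (differences in activation strength are invisible to a\n")
cat("contrast between two equally convergent main effects); the null\n")
cat("scenario should show nothing on either side.\n")
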