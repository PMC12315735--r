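shape <- c(8L, 8L, 8L)
bin <- function(idx) {
  m <- array(FALSE, dim = shape)
  m[idx] <- TRUE
  m
}

test_that("voxel-wise metrics follow their defining ratios", {
  a <- bin(1:4)
  b <- bin(3:5)
  expect_equal(jaccard(a, b), 2 / 5)
  expect_equal(voxel_sensitivity(a, b), 2 / 4)
  expect_equal(voxel_precision(a, b), 2 / 3)

  expect_equal(jaccard(a, a), 1)
  disj <- bin(10:12)
  expect_equal(jaccard(a, disj), 0)
  expect_equal(voxel_sensitivity(a, disj), 0)
  expect_equal(voxel_precision(a, disj), 0)

  full <- bin(1:10)
  expect_equal(voxel_sensitivity(a, full), 1)   # mc superset of cm
  expect_equal(voxel_precision(full, a), 1)     # mc subset of cm
})

test_that("undefined ratios surface as NaN with a warning, never as 0", {
  empty <- bin(integer(0))
  a <- bin(1:3)
  expect_warning(expect_true(is.nan(jaccard(empty, empty))), "empty")
  expect_warning(expect_true(is.nan(voxel_sensitivity(empty, a))), "empty")
  expect_warning(expect_true(is.nan(voxel_precision(a, empty))), "empty")
  expect_error(jaccard(a, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("nested maps give precision 1 and jaccard |mc|/|cm|; roles are symmetric", {
  set.seed(71)
  for (rep in 1:10) {
    cm <- bin(sample(512, 40))
    mc_idx <- sample(which(cm), 10)
    mc <- bin(mc_idx)
    expect_equal(voxel_precision(cm, mc), 1)
    expect_equal(jaccard(cm, mc), sum(mc) / sum(cm))
    other <- bin(sample(512, 30))
    expect_equal(jaccard(cm, other), jaccard(other, cm))
    expect_equal(voxel_sensitivity(cm, other), voxel_precision(other, cm))
  }
})

test_that("cluster overlap counts touching components, per side", {
  # CM: two clusters; MC: one cluster touching only the first
  cm <- array(FALSE, dim = shape)
  cm[1:2, 1, 1] <- TRUE          # cluster 1
  cm[6:7, 6, 6] <- TRUE          # cluster 2
  mc <- array(FALSE, dim = shape)
  mc[2:3, 1, 1] <- TRUE          # touches cluster 1 only
  ov <- cluster_overlap(cm, mc)
  expect_equal(ov$n_cm, 2L)
  expect_equal(ov$n_mc, 1L)
  expect_equal(ov$cluster_sensitivity, 0.5)
  expect_equal(ov$cluster_precision, 1)

  ident <- cluster_overlap(cm, cm)
  expect_equal(ident$cluster_sensitivity, 1)
  expect_equal(ident$cluster_precision, 1)

  far <- array(FALSE, dim = shape)
  far[5, 5, 1] <- TRUE
  both0 <- cluster_overlap(cm, far)
  expect_equal(both0$cluster_sensitivity, 0)
  expect_equal(both0$cluster_precision, 0)

  expect_warning(cluster_overlap(cm, array(FALSE, dim = shape)),
                 "no clusters")
})

test_that("26- and 6-connectivity labelling agree with the flood-fill oracle", {
  set.seed(72)
  for (rep in 1:5) {
    m <- array(stats::runif(512) < 0.15, dim = shape)
    lab <- label_clusters(m, 26L)
    orc <- oracle_label(m)
    # same partition: labels may differ, component memberships may not
    expect_equal(max(lab), max(orc))
    for (i in seq_len(max(lab)))
      expect_equal(length(unique(orc[lab == i])), 1L)
  }
  # diagonal voxels: one cluster under 26, two under 6
  d <- array(FALSE, dim = shape)
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  expect_equal(max(label_clusters(d, 26L)), 1L)
  expect_equal(max(label_clusters(d, 6L)), 2L)
})

test_that("peak extraction finds blob maxima and honours the minimum distance", {
  g <- tiny_grid(16, 4)
  blob <- function(centre_vox, height = 1) {
    vox <- as.matrix(expand.grid(x = 0:15, y = 0:15, z = 0:15))
    d2 <- rowSums(sweep(vox, 2, centre_vox)^2) * 16
    array(height * exp(-d2 / (2 * 36)), dim = g$shape)
  }
  one <- blob(c(8, 8, 8))
  ps <- extract_peaks(one, g, threshold = 0.1)
  expect_equal(nrow(ps$peaks), 1L)
  expect_equal(unname(as.numeric(ps$peaks[1, c("x", "y", "z")])),
               unname(as.numeric(voxel_to_mm(g, c(8L, 8L, 8L)))))

  # two equal blobs 20 mm apart -> 2 peaks
  two_far <- pmax(blob(c(6, 8, 8)), blob(c(11, 8, 8)))
  expect_equal(nrow(extract_peaks(two_far, g, 0.1)$peaks), 2L)

  # 4 mm apart -> merged into a single peak
  two_close <- pmax(blob(c(8, 8, 8)), blob(c(9, 8, 8)))
  expect_equal(nrow(extract_peaks(two_close, g, 0.1)$peaks), 1L)

  # nothing above threshold -> empty set, not an error
  expect_equal(nrow(extract_peaks(one, g, 2)$peaks), 0L)
})

test_that("median nearest-peak distances match the exhaustive oracle", {
  g <- tiny_grid(16, 4)
  mkpeaks <- function(mm) {
    structure(list(peaks = data.frame(x = mm[, 1], y = mm[, 2], z = mm[, 3],
                                      value = rep(1, nrow(mm))),
                   min_separation_mm = 8), class = "peak_set")
  }
  p1 <- mkpeaks(rbind(c(0, 0, 0)))
  p2 <- mkpeaks(rbind(c(10, 0, 0)))
  expect_equal(peak_distances(p1, p2), 10)
  expect_equal(peak_distances(p2, p1), 10)
  expect_equal(peak_distances(p1, p1), 0)

  set.seed(73)
  for (rep in 1:10) {
    from <- matrix(stats::runif(9, -30, 30), 3, 3)
    to <- matrix(stats::runif(6, -30, 30), 2, 3)
    expect_equal(peak_distances(mkpeaks(from), mkpeaks(to)),
                 oracle_median_nn(from, to))
    # rigid translation applied to both sets leaves distances unchanged
    shift <- c(5, -7, 11)
    expect_equal(peak_distances(mkpeaks(sweep(from, 2, -shift)),
                                mkpeaks(sweep(to, 2, -shift))),
                 peak_distances(mkpeaks(from), mkpeaks(to)))
  }
  expect_warning(peak_distances(p1, mkpeaks(matrix(numeric(0), 0, 3))),
                 "empty")
})

test_that("comparing a result with itself yields all-ones ratios and zero distances", {
  set.seed(74)
  k <- kernel_model()
  g <- synthetic_grid()
  centre <- c(0, 16, 8)
  exps <- lapply(1:25, function(i) {
    hit <- centre + stats::runif(3, -5, 5)
    noise <- voxel_to_mm(g, linear_to_voxel_r(g, sample(g$mask_idx, 3)))
    experiment(sprintf("s%02d", i), sample(10:40, 1), rbind(hit, noise))
  })
  cm <- suppressMessages(cfwe_threshold(coordinate_dataset("d", exps),
                                        k, g, n_perm = 150, seed = 4))
  self <- fake_contrast(significant_map(cm), cm$z, alpha = 0.001)
  rep <- compare_maps(cm, self, grid = g)
  expect_equal(rep$jaccard, 1)
  expect_equal(rep$voxel_sensitivity, 1)
  expect_equal(rep$voxel_precision, 1)
  expect_equal(rep$cluster_sensitivity, 1)
  expect_equal(rep$cluster_precision, 1)
  expect_equal(rep$median_dist_cm_to_mc_mm, 0)
  expect_equal(rep$median_dist_mc_to_cm_mm, 0)
})

test_that("comparison reports serialize losslessly to JSON", {
  rep <- structure(
    list(jaccard = 0.25, voxel_sensitivity = 0.5, voxel_precision = 2 / 3,
         n_voxels_cm = 4L, n_voxels_mc = 3L, n_voxels_overlap = 2L,
         n_clusters_cm = 1L, n_clusters_mc = 1L, n_cm_overlapping = 1L,
         n_mc_overlapping = 1L, cluster_sensitivity = 1,
         cluster_precision = 1, median_dist_cm_to_mc_mm = 4.25,
         median_dist_mc_to_cm_mm = 0,
         cm_peaks = data.frame(x = 0, y = 0, z = 0, value = 3.2),
         mc_peaks = data.frame(x = 4, y = 0, z = 0, value = 2.8),
         direction_note = "note", undefined_reasons = list()),
    class = "comparison_report")
  dir <- withr::local_tempdir()
  write_comparison_report(rep, dir)
  back <- jsonlite::read_json(file.path(dir, "comparison_report.json"),
                              simplifyVector = TRUE)
  for (f in c("jaccard", "voxel_sensitivity", "voxel_precision",
              "cluster_sensitivity", "median_dist_cm_to_mc_mm"))
    expect_equal(back[[f]], rep[[f]], tolerance = 1e-12)
  peaks <- read.delim(file.path(dir, "cm_peaks.tsv"))
  expect_equal(peaks$value, 3.2)
})
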