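test_that("a strongly convergent centre survives cluster-level correction", {
  set.seed(41)
  k <- kernel_model()
  g <- synthetic_grid()
  centre <- c(0, 16, 8)
  exps <- lapply(1:25, function(i) {
    hit <- centre + stats::runif(3, -5, 5)
    noise <- voxel_to_mm(g, linear_to_voxel_r(g, sample(g$mask_idx, 3)))
    experiment(sprintf("s%02d", i), sample(10:40, 1), rbind(hit, noise))
  })
  ds <- coordinate_dataset("strong", exps)
  res <- suppressMessages(
    cfwe_threshold(ds, k, g, n_perm = 1000, seed = 99))
  expect_gt(length(res$significant_cluster_ids), 0)
  expect_true(detects_centre(significant_map(res), g, centre, tol = 10))
  # every significant cluster strictly exceeds the 95th-percentile null size
  expect_true(all(res$cluster_table$size[res$cluster_table$significant] >
                    res$cluster_size_cutoff))
})

test_that("the cluster-size null is well-formed and runs are reproducible", {
  set.seed(42)
  k <- kernel_model()
  g <- tiny_grid(12)
  ds <- rand_dataset(g, 6)
  r1 <- suppressMessages(cfwe_threshold(ds, k, g, n_perm = 150, seed = 7))
  r2 <- suppressMessages(cfwe_threshold(ds, k, g, n_perm = 150, seed = 7))
  expect_true(all(r1$cluster_size_null >= 0))
  expect_true(all(r1$cluster_size_null == floor(r1$cluster_size_null)))
  expect_identical(r1$ale, r2$ale)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$cluster_size_null, r2$cluster_size_null)
  expect_identical(r1$significant_cluster_ids, r2$significant_cluster_ids)

  r3 <- suppressMessages(cfwe_threshold(ds, k, g, n_perm = 150, seed = 8))
  expect_false(identical(r1$cluster_size_null, r3$cluster_size_null))
})

test_that("permutation count below 100 is rejected", {
  g <- tiny_grid(8)
  ds <- rand_dataset(g, 3)
  expect_error(cfwe_threshold(ds, kernel_model(), g, n_perm = 50),
               "n_perm")
})

test_that("volumetric outputs round-trip through the writers", {
  set.seed(43)
  k <- kernel_model()
  g <- tiny_grid(12)
  ds <- rand_dataset(g, 5)
  res <- suppressMessages(cfwe_threshold(ds, k, g, n_perm = 120, seed = 3))
  dir <- withr::local_tempdir()
  write_ale_result(res, dir)
  expect_setequal(list.files(dir),
                  c("ale.nii.gz", "p.nii.gz", "z.nii.gz", "clusters.nii.gz",
                    "clusters.tsv", "null_histogram.json"))
  back <- as.array(RNifti::readNifti(file.path(dir, "ale.nii.gz")))
  expect_identical(back[g$mask_idx], res$ale[g$mask_idx])
})
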