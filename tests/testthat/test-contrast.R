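test_that("ALE differences vanish on self-contrast and negate under swapping", {
  set.seed(51)
  k <- kernel_model()
  g <- tiny_grid()
  a <- rand_dataset(g, 3, label = "A")
  b <- rand_dataset(g, 3, label = "B")
  expect_true(all(ale_difference(a, a, k, g) == 0))
  d_ab <- ale_difference(a, b, k, g)
  d_ba <- ale_difference(b, a, k, g)
  expect_identical(d_ab, -d_ba)

  # brute-force oracle from per-experiment MA maps
  ale_or <- function(ds) oracle_ale(lapply(ds$experiments, build_ma_map,
                                           kernel = k, grid = g))
  expect_equal(d_ab, ale_or(a) - ale_or(b), tolerance = 1e-12)
})

test_that("contrasting a dataset with an identical copy finds nothing", {
  set.seed(52)
  k <- kernel_model()
  g <- tiny_grid(12)
  a <- rand_dataset(g, 5, label = "A")
  b <- coordinate_dataset("copy", a$experiments)
  ct <- contrast_permutation_test(a, b, k, g, n_perm = 200, seed = 5)
  expect_true(all(ct$ale_diff == 0))
  expect_equal(sum(ct$significant), 0L)
  # a zero observed difference cannot beat its own permutation distribution
  expect_true(all(ct$p_perm[g$mask] >= 0.05))
  expect_gt(median(ct$p_perm[g$mask]), 0.4)
})

test_that("significant voxels respect mask, extent, and alpha monotonicity", {
  set.seed(53)
  k <- kernel_model()
  g <- synthetic_grid(c(16, 16, 16), 4, "box")
  centre <- c(0, 0, 0)
  mk <- function(lbl, hit) {
    coordinate_dataset(lbl, lapply(1:12, function(i) {
      foci <- voxel_to_mm(g, linear_to_voxel_r(g, sample(g$mask_idx, 3)))
      if (stats::runif(1) < hit)
        foci <- rbind(centre + stats::rnorm(3, sd = 4), foci)
      experiment(sprintf("%s%02d", lbl, i), sample(10:40, 1), foci)
    }))
  }
  a <- mk("a", 0.9)
  b <- mk("b", 0)

  ct_all <- contrast_permutation_test(a, b, k, g, n_perm = 300, seed = 9,
                                      k = 1L)
  # restrictive mask: nothing outside it may be significant
  half <- array(FALSE, dim = g$shape)
  half[1:8, , ] <- TRUE
  ct_mask <- contrast_permutation_test(a, b, k, g, n_perm = 300, seed = 9,
                                       main_effect_mask = half, k = 1L)
  expect_true(all(which(ct_mask$significant) %in% which(half)))
  # masking never adds voxels
  expect_true(all(which(ct_mask$significant) %in% which(ct_all$significant)))

  # extent filtering keeps only components of >= k voxels
  ct_k <- contrast_permutation_test(a, b, k, g, n_perm = 300, seed = 9,
                                    k = 1000L)
  expect_equal(sum(ct_k$significant), 0L)

  # raising alpha never shrinks the significant set
  ct_lo <- contrast_permutation_test(a, b, k, g, n_perm = 300, seed = 9,
                                     alpha = 0.01, k = 1L)
  ct_hi <- contrast_permutation_test(a, b, k, g, n_perm = 300, seed = 9,
                                     alpha = 0.10, k = 1L)
  expect_true(all(which(ct_lo$significant) %in% which(ct_hi$significant)))
})

test_that("input validation catches degenerate contrast setups", {
  g <- tiny_grid(8)
  k <- kernel_model()
  a <- rand_dataset(g, 1, label = "A")
  b <- rand_dataset(g, 2, label = "B")
  expect_error(contrast_permutation_test(a, b, k, g, n_perm = 200), "< 4")
  a5 <- rand_dataset(g, 5, label = "A")
  expect_error(contrast_permutation_test(a5, b, k, g, n_perm = 10), "n_perm")
  expect_error(contrast_permutation_test(a5, b, k, g, n_perm = 200, k = 0),
               "k must be")
  expect_error(contrast_permutation_test(a5, b, k, g, n_perm = 200,
                                         main_effect_mask = array(TRUE, c(2, 2, 2))),
               "same grid")
})

test_that("run_mc composes main effects, masking, and the permutation test", {
  k <- kernel_model()
  g <- synthetic_grid()
  sp <- preset("differential_only", seed = 61)
  a <- suppressMessages(generate_dataset(sp, "A", g))
  b <- suppressMessages(generate_dataset(sp, "B", g))
  mc <- suppressMessages(run_mc(a, b, k, g, n_perm = 300, seed = 62))
  expect_s3_class(mc, "mc_result")
  # every significant voxel lies inside the main-effect mask
  expect_true(all(which(mc$contrast$significant) %in%
                    which(mc$main_effect_mask)))
  # differential scenario: the contrast finds the centre region
  expect_gt(sum(mc$contrast$significant), 0)
  expect_true(detects_centre(mc$contrast$significant, g, c(0, 16, 8)))

  dir <- withr::local_tempdir()
  write_mc_result(mc, dir)
  expect_true(all(c("diff.nii.gz", "p_perm.nii.gz", "z.nii.gz",
                    "significant.nii.gz", "settings.json") %in%
                    list.files(dir)))
  # output volumes carry the grid affine
  img <- RNifti::readNifti(file.path(dir, "diff.nii.gz"))
  expect_equal(unname(unclass(RNifti::xform(img)))[1:3, 1:3],
               unname(g$affine[1:3, 1:3]), tolerance = 1e-6)
})
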