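test_that("grid constructor validates shape, affine, and mask", {
  aff <- diag(c(4, 4, 4, 1))
  mask <- array(TRUE, dim = c(4, 4, 4))
  g <- brain_grid(c(4, 4, 4), aff, mask)
  expect_equal(length(g$mask_idx), 64L)
  expect_equal(g$voxel_mm, c(4, 4, 4))

  expect_error(brain_grid(c(4, 4), aff, mask), "3 positive integers")
  expect_error(brain_grid(c(4, 4, 4), diag(4) * 0, mask), "invertible")
  expect_error(brain_grid(c(4, 4, 4), aff, array(FALSE, c(4, 4, 4))),
               "at least one voxel")
})

test_that("mm/voxel transforms invert each other exactly at voxel centres", {
  g <- synthetic_grid(c(16, 20, 12), 4)
  vox <- rbind(c(0L, 0L, 0L), c(15L, 19L, 11L), c(7L, 3L, 5L))
  mm <- voxel_to_mm(g, vox)
  expect_equal(mm_to_voxel(g, mm), vox)
  expect_lt(max(abs(voxel_to_mm(g, mm_to_voxel(g, mm)) - mm)), 1e-9)
})

test_that("NIfTI mask round-trips through write_mask and load_grid", {
  g <- synthetic_grid(c(16, 16, 16), 4, "ellipsoid")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(g, f)
  g2 <- load_grid(f)
  expect_equal(g2$shape, g$shape)
  expect_equal(unname(g2$affine), unname(g$affine), tolerance = 1e-6)
  expect_identical(g2$mask, g$mask)
})

test_that("load_grid rejects empty and non-3D volumes", {
  zero <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, dim = c(8, 8, 8)))
  RNifti::writeNifti(img, zero)
  expect_error(load_grid(zero), "empty")

  four_d <- withr::local_tempfile(fileext = ".nii.gz")
  img4 <- RNifti::asNifti(array(1, dim = c(4, 4, 4, 2)))
  RNifti::writeNifti(img4, four_d)
  expect_error(load_grid(four_d), "3-D")
})

test_that("write_map preserves in-mask values bit-exactly and zeroes the rest", {
  g <- synthetic_grid(c(12, 12, 12), 4, "ellipsoid")
  vol <- array(stats::runif(prod(g$shape)), dim = g$shape)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_map(vol, g, f)
  back <- as.array(RNifti::readNifti(f))
  expect_identical(back[g$mask_idx], vol[g$mask_idx])
  expect_true(all(back[!g$mask] == 0))

  ones <- array(1, dim = g$shape)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_map(ones, g, f2)
  expect_equal(sum(as.array(RNifti::readNifti(f2)) > 0),
               length(g$mask_idx))
})

test_that("write_map rejects shape mismatch and non-finite in-mask values", {
  g <- synthetic_grid(c(12, 12, 12), 4)
  expect_error(write_map(array(0, c(4, 4, 4)), g, tempfile()), "shape")
  bad <- array(0, dim = g$shape)
  bad[g$mask_idx[1]] <- NaN
  expect_error(write_map(bad, g, tempfile()), "non-finite")
})
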