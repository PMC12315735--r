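#' Voxel grid with analysis mask
#'
#' A `brain_grid` couples a 3-D voxel lattice to millimetre space: the grid
#' shape, a 4x4 affine mapping 0-based voxel indices to mm coordinates
#' (NIfTI convention), and a logical analysis mask (e.g. grey matter) on the
#' lattice. All ALE computation is restricted to in-mask voxels.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param affine Numeric 4x4 matrix mapping homogeneous 0-based voxel indices
#'   to mm; must be invertible with strictly positive voxel sizes.
#' @param mask Logical array of dimension `shape` with at least one `TRUE`
#'   voxel.
#' @return An object of class `brain_grid` with elements `shape`, `affine`,
#'   `mask`, `mask_idx` (linear indices of in-mask voxels) and `voxel_mm`
#'   (per-axis voxel size in mm).
#' @export
brain_grid <- function(shape, affine, mask) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("`affine` must be invertible")
  voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_mm <= 0)) stop("voxel size must be strictly positive on each axis")
  mask <- array(as.logical(mask), dim = shape)
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(
    list(shape = shape, affine = affine, mask = mask,
         mask_idx = which(mask), voxel_mm = voxel_mm),
    class = "brain_grid"
  )
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf("<brain_grid> %s voxels @ %s mm, %d in mask\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x"),
              length(x$mask_idx)))
  invisible(x)
}

#' Synthetic analysis grid
#'
#' Builds a self-contained grid (no external mask file needed) with an
#' ellipsoidal "brain-like" or box mask, centred on the mm origin. The
#' default, a 32 x 38 x 32 lattice at 4 mm with an ellipsoid of semi-axes
#' 60 x 72 x 60 mm (~17k in-mask voxels), is roughly the size of an adult
#' grey-matter mask sampled at 4 mm.
#'
#' @param shape Grid dimensions in voxels.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param type `"ellipsoid"` (default) or `"box"` (all voxels in mask).
#' @return A [brain_grid].
#' @export
synthetic_grid <- function(shape = c(32L, 38L, 32L), voxel_mm = 4,
                           type = c("ellipsoid", "box")) {
  type <- match.arg(type)
  shape <- as.integer(shape)
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (shape - 1L) / 2
  if (type == "box") {
    mask <- array(TRUE, dim = shape)
  } else {
    semi <- voxel_mm * (shape - 1L) / 2 * 0.95
    ix <- seq_len(shape[1]) - 1L
    iy <- seq_len(shape[2]) - 1L
    iz <- seq_len(shape[3]) - 1L
    xx <- (voxel_mm * ix + affine[1, 4]) / semi[1]
    yy <- (voxel_mm * iy + affine[2, 4]) / semi[2]
    zz <- (voxel_mm * iz + affine[3, 4]) / semi[3]
    mask <- outer(outer(xx^2, yy^2, `+`), zz^2, `+`) <= 1
  }
  brain_grid(shape, affine, mask)
}

#' Convert mm coordinates to voxel indices
#'
#' Applies the inverse affine and rounds to the nearest voxel (0-based
#' indices). Coordinates are not required to fall inside the grid.
#'
#' @param grid A [brain_grid].
#' @param mm Numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return Integer matrix (n x 3) of 0-based voxel indices.
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3)
  inv <- solve(grid$affine)
  hom <- cbind(mm, 1) %*% t(inv)
  matrix(as.integer(round(hom[, 1:3, drop = FALSE])), ncol = 3)
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid A [brain_grid].
#' @param voxel Integer matrix (n x 3) or length-3 vector of 0-based voxel
#'   indices.
#' @return Numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(grid, voxel) {
  voxel <- matrix(as.numeric(voxel), ncol = 3)
  hom <- cbind(voxel, 1) %*% t(grid$affine)
  hom[, 1:3, drop = FALSE]
}

# linear (1-based) array index for 0-based voxel triples; NA outside the grid
voxel_to_linear <- function(grid, voxel) {
  voxel <- matrix(as.integer(voxel), ncol = 3)
  ok <- voxel[, 1] >= 0L & voxel[, 1] < grid$shape[1] &
    voxel[, 2] >= 0L & voxel[, 2] < grid$shape[2] &
    voxel[, 3] >= 0L & voxel[, 3] < grid$shape[3]
  out <- rep(NA_integer_, nrow(voxel))
  out[ok] <- 1L + voxel[ok, 1] +
    grid$shape[1] * (voxel[ok, 2] + grid$shape[2] * voxel[ok, 3])
  out
}

# 0-based voxel triples for linear (1-based) array indices
linear_to_voxel <- function(grid, idx) {
  idx0 <- as.integer(idx) - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cbind(idx0 %% nx, (idx0 %/% nx) %% ny, idx0 %/% (nx * ny))
}

#' Load a grid from a NIfTI mask
#'
#' Reads a 3-D NIfTI-1 volume; strictly positive voxels define the analysis
#' mask.
#'
#' @param mask_path Path to a NIfTI-1 file.
#' @return A [brain_grid].
#' @export
load_grid <- function(mask_path) {
  img <- RNifti::readNifti(mask_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("mask volume must be 3-D, got ", length(dim(arr)), " dimensions")
  mask <- arr > 0
  if (!any(mask)) stop("mask is empty: no strictly positive voxel")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  brain_grid(dim(arr), affine, mask)
}

#' Write a per-voxel scalar field as NIfTI
#'
#' Out-of-mask voxels are written as 0. NaN/NA inside the mask is an error:
#' result maps must be fully defined where they claim support.
#'
#' @param volume Numeric array matching the grid shape.
#' @param grid A [brain_grid].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(volume, grid, path) {
  volume <- as.array(volume)
  if (!identical(as.integer(dim(volume)), grid$shape))
    stop("volume shape does not match grid shape")
  if (anyNA(volume[grid$mask_idx]) || any(!is.finite(volume[grid$mask_idx])))
    stop("volume contains non-finite values inside the mask")
  out <- array(0, dim = grid$shape)
  out[grid$mask_idx] <- volume[grid$mask_idx]
  img <- RNifti::asNifti(out)
  img <- RNifti::`pixdim<-`(img, grid$voxel_mm)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a grid's mask as a NIfTI volume
#'
#' @param grid A [brain_grid].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(grid, path) {
  write_map(array(as.numeric(grid$mask), dim = grid$shape), grid, path)
}
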