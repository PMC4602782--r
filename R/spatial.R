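#' Voxel/world coordinate mapping
#'
#' Voxel indices are 0-based, following the NIfTI convention; the affine maps
#' homogeneous 0-based indices to world (MNI) millimetre coordinates. R arrays
#' are 1-based, so the helpers below take and return 1-based array indices and
#' subtract/add the offset internally.
#'
#' @param affine invertible 4x4 matrix mapping 0-based voxel indices to mm.
#' @param ijk integer matrix (n x 3) of 1-based array indices (rows), or a
#'   length-3 vector.
#' @param xyz numeric matrix (n x 3) of mm coordinates, or a length-3 vector.
#' @return `vox_to_mm`: n x 3 matrix of mm coordinates. `mm_to_vox`: n x 3
#'   matrix of fractional 1-based array indices.
#' @examples
#' aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-60, -76, -22)
#' vox_to_mm(aff, c(1, 1, 1))      # grid corner -> origin mm
#' mm_to_vox(aff, c(-60, -76, -22))
#' @export
vox_to_mm <- function(affine, ijk) {
  ijk <- rbind_coords(ijk)
  hom <- cbind(ijk - 1, 1)                       # to 0-based homogeneous
  out <- hom %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @export
mm_to_vox <- function(affine, xyz) {
  xyz <- rbind_coords(xyz)
  hom <- cbind(xyz, 1)
  out <- hom %*% t(solve(affine))
  out[, 1:3, drop = FALSE] + 1                   # back to 1-based
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else
    matrix(as.numeric(x), ncol = ncol(x))
}

check_affine <- function(affine) {
  dmn_assert(is.matrix(affine) && all(dim(affine) == c(4, 4)),
             "bad_affine", "affine must be a 4x4 matrix")
  d <- det(affine)
  dmn_assert(is.finite(d) && abs(d) > .Machine$double.eps,
             "bad_affine", "affine is not invertible")
  invisible(affine)
}

# voxel edge lengths implied by an affine (mm per axis step)
affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim_spatial(a) == dim_spatial(b)) &&
    max(abs(attr_affine(a) - attr_affine(b))) < tol
}

dim_spatial <- function(x) {
  if (inherits(x, "bold_series")) dim(x$data)[1:3]
  else dim(x$data)
}

attr_affine <- function(x) x$affine

# mm coordinates of every voxel centre on a grid, as an n x 3 matrix in
# column-major (R array) order.
grid_mm_coords <- function(shape, affine) {
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  vox_to_mm(affine, idx)
}

# logical vector (column-major) of voxels whose centre lies within radius_mm
# of center_mm
sphere_voxels <- function(shape, affine, center_mm, radius_mm) {
  mm <- grid_mm_coords(shape, affine)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  d2 <= radius_mm^2 + 1e-9
}
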