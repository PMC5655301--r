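#' Image grid geometry
#'
#' An `image_grid` ties a 3D voxel lattice to millimetre space through a
#' 4x4 affine. Voxel indices are 0-based throughout the package; millimetre
#' coordinates follow the NIfTI affine convention (RAS+ for all synthetic
#' data this package generates).
#'
#' @param dims integer triple, number of voxels along x, y, z (all >= 1).
#' @param voxel_size_mm positive real triple, voxel edge lengths in mm.
#'   Ignored when `affine` is supplied (then derived from its column norms).
#' @param origin_mm mm coordinate of voxel (0,0,0); used only when `affine`
#'   is not supplied.
#' @param affine optional 4x4 matrix mapping 0-based voxel indices to mm.
#' @return An object of class `image_grid` with fields `dims`,
#'   `voxel_size_mm` and `affine`.
#' @examples
#' g <- image_grid(c(24, 28, 24), 3, origin_mm = c(-36, -89, -4))
#' voxel_to_mm(g, c(8, 14, 12))   # (-12, -47, 32)
#' @export
image_grid <- function(dims, voxel_size_mm = c(3, 3, 3), origin_mm = c(0, 0, 0),
                       affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  if (is.null(affine)) {
    voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
    stopifnot(all(voxel_size_mm > 0))
    affine <- diag(c(voxel_size_mm, 1))
    affine[1:3, 4] <- as.numeric(origin_mm)
  } else {
    affine <- as.matrix(affine)
    stopifnot(identical(dim(affine), c(4L, 4L)))
    if (abs(det(affine)) < .Machine$double.eps * 100)
      stop("grid affine must be invertible")
    voxel_size_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) < tol
}

#' Convert between voxel indices and mm coordinates
#'
#' `voxel_to_mm()` maps 0-based voxel indices through the grid affine;
#' `mm_to_voxel()` applies the inverse. The two are mutually inverse for any
#' invertible affine. Both accept a triple or an n x 3 matrix.
#'
#' @param grid an [image_grid].
#' @param index 0-based voxel index triple (or n x 3 matrix); need not be
#'   integral.
#' @param coord_mm mm coordinate triple (or n x 3 matrix).
#' @return A numeric triple, or an n x 3 matrix matching the input shape.
#' @export
voxel_to_mm <- function(grid, index) {
  idx <- if (is.matrix(index)) t(index) else matrix(as.numeric(index), nrow = 3)
  out <- grid$affine[1:3, 1:3] %*% idx + grid$affine[1:3, 4]
  if (is.matrix(index)) t(out) else as.numeric(out)
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(grid, coord_mm) {
  inv <- solve(grid$affine)
  cm <- if (is.matrix(coord_mm)) t(coord_mm) else matrix(as.numeric(coord_mm), nrow = 3)
  out <- inv[1:3, 1:3] %*% cm + inv[1:3, 4]
  if (is.matrix(coord_mm)) t(out) else as.numeric(out)
}

#' mm coordinates of every voxel centre
#'
#' @param grid an [image_grid].
#' @return An (nx*ny*nz) x 3 matrix of voxel-centre mm coordinates in array
#'   (column-major) order.
#' @keywords internal
grid_coords_mm <- function(grid) {
  d <- grid$dims
  idx <- cbind(rep(0:(d[1] - 1L), times = d[2] * d[3]),
               rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
               rep(0:(d[3] - 1L), each = d[1] * d[2]))
  voxel_to_mm(grid, idx)
}
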