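#' Brain masks
#'
#' A `brain_mask` is a logical 3D array tied to an [image_grid]. All
#' statistical operations in the package are restricted to in-mask voxels;
#' out-of-mask voxels never influence in-mask results.
#'
#' @param grid an [image_grid].
#' @param inside logical array with dimensions `grid$dims`; must contain at
#'   least one `TRUE` voxel.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(grid, inside) {
  stopifnot(inherits(grid, "image_grid"))
  inside <- array(as.logical(inside), dim = grid$dims)
  if (anyNA(inside)) stop("mask must not contain NA")
  if (!any(inside)) stop("mask must contain at least one voxel")
  structure(list(grid = grid, inside = inside), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d of %d voxels inside\n",
              sum(x$inside), prod(x$grid$dims)))
  invisible(x)
}

#' Ellipsoidal brain mask
#'
#' A smooth convex stand-in for a brain outline on small synthetic grids:
#' voxels whose centre lies inside the axis-aligned ellipsoid inscribed in
#' the grid bounding box, shrunk by `margin` voxels on every side.
#'
#' @param grid an [image_grid].
#' @param margin shrinkage from the bounding box, in voxels.
#' @return A [brain_mask].
#' @export
ellipsoid_mask <- function(grid, margin = 1) {
  d <- grid$dims
  semi <- (d - 1) / 2 - margin
  if (any(semi <= 0)) stop("grid too small for ellipsoid mask with this margin")
  ctr <- (d - 1) / 2
  ax <- ((0:(d[1] - 1L) - ctr[1]) / semi[1])^2
  ay <- ((0:(d[2] - 1L) - ctr[2]) / semi[2])^2
  az <- ((0:(d[3] - 1L) - ctr[3]) / semi[3])^2
  inside <- outer(outer(ax, ay, "+"), az, "+") <= 1
  brain_mask(grid, inside)
}

#' Spherical region-of-interest mask
#'
#' Selects voxels whose centre-to-centre Euclidean distance in mm from
#' `center_mm` is at most `radius_mm` (a `<=` comparison; no partial-volume
#' weighting), optionally intersected with a brain mask.
#'
#' @param grid an [image_grid].
#' @param center_mm sphere centre, mm triple.
#' @param radius_mm sphere radius in mm (> 0).
#' @param brain optional [brain_mask] to intersect with.
#' @return A [brain_mask] covering the sphere.
#' @export
sphere_mask <- function(grid, center_mm, radius_mm, brain = NULL) {
  stopifnot(radius_mm > 0)
  xyz <- grid_coords_mm(grid)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  inside <- array(d2 <= radius_mm^2, dim = grid$dims)
  if (!is.null(brain)) {
    if (!same_grid(grid, brain$grid)) stop("sphere and brain mask grids differ")
    inside <- inside & brain$inside
  }
  if (!any(inside)) stop("sphere mask is empty on this grid")
  brain_mask(grid, inside)
}
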