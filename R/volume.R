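#' 4D BOLD volume
#'
#' One subject's BOLD series: a 4D numeric array (x, y, z, time) on an
#' [image_grid] with a repetition time in seconds.
#'
#' @param values numeric 4D array.
#' @param grid an [image_grid] matching the first three dimensions.
#' @param tr_seconds repetition time in seconds (> 0).
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(values, grid, tr_seconds) {
  stopifnot(inherits(grid, "image_grid"), length(dim(values)) == 4L,
            tr_seconds > 0)
  if (!identical(as.integer(dim(values)[1:3]), grid$dims))
    stop("volume dimensions do not match grid")
  structure(list(values = values, grid = grid,
                 n_timepoints = dim(values)[4],
                 tr_seconds = as.numeric(tr_seconds)),
            class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  cat(sprintf("<bold_volume> %d x %d x %d voxels, %d timepoints, TR %.3g s\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$n_timepoints, x$tr_seconds))
  invisible(x)
}

# timepoints-by-voxels matrix of the in-mask series (column order follows
# which(mask$inside))
vol_matrix <- function(vol, mask) {
  if (!same_grid(vol$grid, mask$grid)) stop("volume and mask grids differ")
  flat <- matrix(vol$values, nrow = prod(vol$grid$dims))
  t(flat[which(mask$inside), , drop = FALSE])
}

# write a timepoints-by-voxels matrix back into the in-mask voxels of a
# zero-filled 4D array
matrix_to_vol <- function(mat, vol, mask) {
  flat <- matrix(vol$values, nrow = prod(vol$grid$dims))
  flat[which(mask$inside), ] <- t(mat)
  flat[which(!mask$inside), ] <- 0
  bold_volume(array(flat, dim = dim(vol$values)), vol$grid, vol$tr_seconds)
}

#' Voxelwise statistic map
#'
#' A scalar per in-mask voxel with a kind label constraining its range:
#' `W` (Kendall concordance, in [0,1]), `r` (correlation, in [-1,1]),
#' `z`, `t` (unbounded), `p` (in [0,1]).
#'
#' @param values numeric 3D array on the mask grid; out-of-mask entries are
#'   forced to zero.
#' @param mask a [brain_mask].
#' @param kind one of `"W"`, `"r"`, `"z"`, `"t"`, `"p"`.
#' @param meta named list of provenance (subject id, contrast, parameters,
#'   degrees of freedom, flagged voxels...).
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, mask, kind = c("W", "r", "z", "t", "p"),
                     meta = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(mask, "brain_mask"))
  values <- array(as.numeric(values), dim = mask$grid$dims)
  values[!mask$inside] <- 0
  v <- values[mask$inside]
  if (anyNA(v) || any(!is.finite(v))) stop("stat_map values must be finite")
  rng <- switch(kind, W = c(0, 1), r = c(-1, 1), p = c(0, 1), c(-Inf, Inf))
  if (any(v < rng[1] - 1e-12) || any(v > rng[2] + 1e-12))
    stop(sprintf("'%s' map values outside [%g, %g]", kind, rng[1], rng[2]))
  structure(list(values = values, grid = mask$grid, mask = mask, kind = kind,
                 meta = meta), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$mask$inside]
  cat(sprintf("<stat_map:%s> %d voxels, range [%.4g, %.4g]\n",
              x$kind, length(v), min(v), max(v)))
  invisible(x)
}

#' In-mask values of a stat map
#' @param map a [stat_map].
#' @return Numeric vector of the in-mask voxel values.
#' @export
map_values <- function(map) map$values[map$mask$inside]
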