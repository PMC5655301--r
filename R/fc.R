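#' Seed specification for connectivity analysis
#'
#' Defaults place a 10 mm-radius sphere at the precuneus centre
#' (-12, -47, 32) in MNI mm, the posterior node of the default mode
#' network.
#'
#' @param center_mm seed centre, mm triple.
#' @param radius_mm seed radius in mm (> 0).
#' @return A list of class `seed_spec`.
#' @export
seed_spec <- function(center_mm = c(-12, -47, 32), radius_mm = 10) {
  stopifnot(length(center_mm) == 3L, radius_mm > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm)),
            class = "seed_spec")
}

#' Build the seed voxel mask
#'
#' Voxels whose centre lies within `radius_mm` of the seed centre (`<=`
#' comparison, no partial-volume weighting), intersected with the brain
#' mask. An empty intersection is a seed-placement error.
#'
#' @param grid an [image_grid].
#' @param spec a [seed_spec].
#' @param brain optional [brain_mask] to intersect with.
#' @return A [brain_mask] for the seed region.
#' @export
seed_mask <- function(grid, spec = seed_spec(), brain = NULL) {
  tryCatch(sphere_mask(grid, spec$center_mm, spec$radius_mm, brain),
           error = function(e)
             stop("seed placement yields no in-brain voxels: ",
                  conditionMessage(e)))
}

#' Mean time series over a seed region
#'
#' @param vol a [bold_volume].
#' @param seed a [brain_mask] marking the seed voxels.
#' @return Numeric vector: the unweighted mean across seed voxels at each
#'   timepoint.
#' @export
seed_timeseries <- function(vol, seed) {
  X <- vol_matrix(vol, seed)
  rowMeans(X)
}

#' Voxelwise Pearson correlation with a reference series
#'
#' Sample Pearson correlation between each in-mask voxel's series and the
#' seed series. Constant voxel series get r = 0 and are flagged in
#' `meta$constant_voxels`.
#'
#' @param vol a [bold_volume] with at least 3 timepoints.
#' @param seed_series numeric reference series (must not be constant).
#' @param mask a [brain_mask].
#' @return A [stat_map] of kind `"r"`.
#' @export
pearson_map <- function(vol, seed_series, mask) {
  stopifnot(inherits(vol, "bold_volume"))
  n <- vol$n_timepoints
  if (n < 3L) stop("need at least 3 timepoints")
  if (length(seed_series) != n) stop("seed series length mismatch")
  s <- seed_series - mean(seed_series)
  ss <- sqrt(sum(s^2))
  if (ss == 0) stop("seed series is constant")
  X <- vol_matrix(vol, mask)
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  r <- as.numeric(crossprod(s, Xc)) / (ss * sx)
  const <- sx == 0
  r[const] <- 0
  r <- pmin(pmax(r, -1), 1)
  out <- array(0, dim = mask$grid$dims)
  out[mask$inside] <- r
  stat_map(out, mask, "r",
           meta = list(n = n, constant_voxels = which(const)))
}

#' Fisher r-to-z transform
#'
#' The variance-stabilising transform z = arctanh(r) =
#' (1/2) ln((1+r)/(1-r)), applied per voxel. Correlations of magnitude 1
#' (possible when a voxel equals the seed series exactly) are clamped to
#' +/- arctanh(1 - 1e-7) and flagged in `meta$clamped_voxels`. The
#' `"printed"` variant returns the raw ratio (1+r)/(1-r); it is not a
#' variance-stabilising transform and is provided for comparison only —
#' do not feed it to normal-theory tests.
#'
#' @param r_map a [stat_map] of kind `"r"`, or a bare numeric vector.
#' @param variant `"fisher"` (default) or `"printed"`.
#' @return A [stat_map] of kind `"z"` (or a numeric vector for vector
#'   input).
#' @export
fisher_z <- function(r_map, variant = c("fisher", "printed")) {
  variant <- match.arg(variant)
  vec_in <- is.numeric(r_map)
  r <- if (vec_in) r_map else {
    stopifnot(identical(r_map$kind, "r"))
    map_values(r_map)
  }
  lim <- 1 - 1e-7
  clamped <- which(abs(r) >= lim)
  r <- pmin(pmax(r, -lim), lim)
  z <- if (variant == "fisher") atanh(r) else (1 + r) / (1 - r)
  if (vec_in) return(z)
  out <- array(0, dim = r_map$mask$grid$dims)
  out[r_map$mask$inside] <- z
  stat_map(out, r_map$mask, "z",
           meta = c(r_map$meta,
                    list(variant = variant, clamped_voxels = clamped)))
}

#' Per-subject seed connectivity map
#'
#' Convenience wrapper: seed mask, mean seed series, voxelwise correlation,
#' Fisher transform.
#'
#' @param vol a preprocessed [bold_volume].
#' @param mask a [brain_mask].
#' @param spec a [seed_spec].
#' @return A list with `r` and `z` [stat_map]s and the seed mask.
#' @export
seed_fc_maps <- function(vol, mask, spec = seed_spec()) {
  sm <- seed_mask(vol$grid, spec, mask)
  ts <- seed_timeseries(vol, sm)
  r <- pearson_map(vol, ts, mask)
  list(r = r, z = fisher_z(r), seed = sm)
}
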