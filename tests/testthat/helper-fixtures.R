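# Shared fixtures: everything is built in code at test time.

# tiny grid with an interior ellipsoidal mask
tiny_grid <- function(dims = c(8L, 8L, 8L), vox = 3, origin = c(0, 0, 0)) {
  image_grid(dims, vox, origin_mm = origin)
}

full_mask <- function(grid) brain_mask(grid, array(TRUE, grid$dims))

# volume with iid N(0,1) voxels
noise_volume <- function(grid, nt = 20L, tr = 3, seed = 1L) {
  set.seed(seed)
  bold_volume(array(rnorm(prod(grid$dims) * nt), c(grid$dims, nt)), grid, tr)
}

# a volume whose every voxel carries `series`
constant_series_volume <- function(grid, series, tr = 3) {
  nt <- length(series)
  arr <- array(rep(series, each = prod(grid$dims)), c(grid$dims, nt))
  bold_volume(arr, grid, tr)
}

# desk-scale cohort spec small enough for pipeline tests: 14^3 grid at 3 mm,
# 60 acquired timepoints, small-radius effect spheres
small_spec <- function(n_timepoints_acquired = 60L, ...) {
  g <- image_grid(c(14L, 14L, 14L), 3, origin_mm = c(-21, -21, -21))
  cohort_spec(
    grid = g, n_timepoints_acquired = n_timepoints_acquired,
    seed_center_mm = c(-6, 0, 0),
    dmn_rois = list(list(center_mm = c(-6, 0, 0), radius_mm = 6),
                    list(center_mm = c(6, 6, 6), radius_mm = 6)),
    reho_effect_rois = list(list(center_mm = c(0, -9, 6), radius_mm = 6)),
    ...)
}

small_seed_spec <- function() seed_spec(center_mm = c(-6, 0, 0), radius_mm = 6)

# brute-force 3D Gaussian convolution restricted to a mask (oracle for
# gaussian_smooth): direct sum over the full kernel support
brute_gaussian_smooth <- function(arr3, fwhm_mm, vox_mm, inside) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox_mm
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  d <- dim(arr3)
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!inside[x, y, z]) next
    num <- 0; den <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      i <- x + dx; j <- y + dy; l <- z + dz
      if (i < 1 || j < 1 || l < 1 || i > d[1] || j > d[2] || l > d[3]) next
      if (!inside[i, j, l]) next
      w <- k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
      num <- num + w * arr3[i, j, l]
      den <- den + w
    }
    out[x, y, z] <- num / den
  }
  out
}

# deviation-form oracle for Kendall's W: 12 S / (K^2 (n^3 - n))
kendall_w_oracle <- function(ranks) {
  K <- nrow(ranks); n <- ncol(ranks)
  Ri <- colSums(ranks)
  S <- sum((Ri - mean(Ri))^2)
  12 * S / (K^2 * (n^3 - n))
}
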