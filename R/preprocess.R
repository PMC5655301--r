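#' Preprocessing configuration
#'
#' Defaults follow the acquisition and cleaning protocol the package
#' implements: discard the first 5 volumes (scanner equilibration), exclude
#' subjects moving more than 10 mm or rotating more than 1 degree on any
#' axis, smooth with an 8 mm FWHM isotropic Gaussian, remove the per-voxel
#' linear trend, and keep only the 0.01-0.08 Hz band.
#'
#' @param n_discard initial volumes to drop (>= 0).
#' @param max_translation_mm motion QC limit, mm per axis.
#' @param max_rotation_deg motion QC limit, degrees per axis.
#' @param fwhm_mm Gaussian smoothing kernel full width at half maximum, mm
#'   (0 disables smoothing).
#' @param band_hz length-2 passband in Hz, low < high.
#' @param stage_order `"presmooth"` smooths the series before computing
#'   homogeneity maps; `"conventional"` computes homogeneity on unsmoothed
#'   series and smooths the resulting map instead (connectivity always uses
#'   smoothed series).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 5L, max_translation_mm = 10,
                              max_rotation_deg = 1, fwhm_mm = 8,
                              band_hz = c(0.01, 0.08),
                              stage_order = c("presmooth", "conventional")) {
  stage_order <- match.arg(stage_order)
  stopifnot(n_discard >= 0, max_translation_mm > 0, max_rotation_deg > 0,
            fwhm_mm >= 0, length(band_hz) == 2L)
  if (!(0 < band_hz[1] && band_hz[1] < band_hz[2]))
    stop("band must satisfy 0 < low < high")
  structure(list(n_discard = as.integer(n_discard),
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 fwhm_mm = fwhm_mm, band_hz = as.numeric(band_hz),
                 stage_order = stage_order),
            class = "preprocess_config")
}

#' Discard initial timepoints
#'
#' @param vol a [bold_volume].
#' @param n_discard number of leading timepoints to remove; must be smaller
#'   than the series length.
#' @return A [bold_volume] with the remaining timepoints in order.
#' @export
discard_initial <- function(vol, n_discard = 5L) {
  stopifnot(inherits(vol, "bold_volume"), n_discard >= 0)
  if (n_discard >= vol$n_timepoints)
    stop(sprintf("cannot discard %d of %d timepoints", n_discard,
                 vol$n_timepoints))
  if (n_discard == 0L) return(vol)
  bold_volume(vol$values[, , , (n_discard + 1L):vol$n_timepoints, drop = FALSE],
              vol$grid, vol$tr_seconds)
}

#' Head-motion quality control
#'
#' A subject fails if the maximum absolute translation on any axis reaches
#' `max_translation_mm`, or the maximum absolute rotation on any axis
#' reaches `max_rotation_deg` (rotations are stored in radians and
#' converted for the comparison). Limits are evaluated per axis.
#'
#' @param trace a [motion_trace].
#' @param cfg a [preprocess_config] carrying the limits.
#' @return A list with `pass` (logical), `max_translation_mm` and
#'   `max_rotation_deg` (the observed maxima).
#' @export
qc_motion <- function(trace, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "motion_trace"))
  max_t <- max(abs(trace$translations_mm))
  max_r <- max(abs(trace$rotations_rad)) * 180 / pi
  list(pass = max_t < cfg$max_translation_mm && max_r < cfg$max_rotation_deg,
       max_translation_mm = max_t, max_rotation_deg = max_r)
}

# 1D Gaussian kernel in voxel units, truncated at 4 sigma
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a (d[1],d[2],d[3],nt) array along one spatial axis with zero
# padding, via a banded matrix product
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (off in -r:r) {
    i <- max(1L, 1L - off):min(n, n - off)
    C[cbind(i, i + off)] <- kernel[off + r + 1L]
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  a <- C %*% matrix(a, nrow = n)
  dim(a) <- d[perm]
  aperm(a, order(perm))
}

#' Isotropic Gaussian spatial smoothing
#'
#' Each timepoint is convolved with a separable Gaussian of
#' sigma = fwhm / (2 sqrt(2 ln 2)) mm, converted to voxel units per axis.
#' The kernel is renormalised over the in-mask support (the masked image is
#' smoothed and divided by the smoothed mask), so a constant in-mask image
#' remains exactly constant and out-of-mask voxels never leak in.
#'
#' @param vol a [bold_volume] (or a [stat_map], smoothed as one frame).
#' @param fwhm_mm kernel FWHM in mm; 0 is the identity.
#' @param mask a [brain_mask].
#' @return An object of the same class as `vol`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, mask) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (inherits(vol, "stat_map")) {
    v4 <- bold_volume(array(vol$values, dim = c(dim(vol$values), 1L)),
                      vol$grid, 1)
    sm <- gaussian_smooth(v4, fwhm_mm, mask)
    return(stat_map(sm$values[, , , 1L], mask, vol$kind, vol$meta))
  }
  stopifnot(inherits(vol, "bold_volume"))
  if (!same_grid(vol$grid, mask$grid)) stop("volume and mask grids differ")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(1:3, function(a)
    gauss_kernel_1d(sigma_mm / vol$grid$voxel_size_mm[a]))
  m <- array(0, dim = dim(vol$values))
  m[] <- as.numeric(mask$inside)              # recycled over time
  num <- vol$values * m
  den <- m
  for (a in 1:3) {
    num <- conv_axis(num, kernels[[a]], a)
    den <- conv_axis(den, kernels[[a]], a)
  }
  out <- array(0, dim = dim(vol$values))
  keep <- m > 0
  out[keep] <- num[keep] / den[keep]
  bold_volume(out, vol$grid, vol$tr_seconds)
}

#' Remove per-voxel linear trend
#'
#' Fits intercept + slope against time by least squares at every in-mask
#' voxel and returns the residuals: output series have zero mean and zero
#' linear trend. Removing the mean as well as the slope leaves correlations
#' and rank concordance untouched.
#'
#' @param vol a [bold_volume] with at least 3 timepoints.
#' @param mask a [brain_mask].
#' @return A [bold_volume]; out-of-mask voxels are zeroed.
#' @export
detrend_linear <- function(vol, mask) {
  stopifnot(inherits(vol, "bold_volume"))
  n <- vol$n_timepoints
  if (n < 3L) stop("detrending needs at least 3 timepoints")
  X <- vol_matrix(vol, mask)                  # time x voxels
  tc <- seq_len(n) - (n + 1) / 2
  Xc <- sweep(X, 2, colMeans(X))
  slope <- crossprod(tc, Xc) / sum(tc^2)      # 1 x voxels
  res <- Xc - outer(tc, as.numeric(slope))
  matrix_to_vol(res, vol, mask)
}

#' Ideal band-pass filter
#'
#' Per-voxel discrete Fourier transform with every coefficient whose
#' frequency f_k = k/(n TR) lies strictly below the band's low edge or
#' strictly above its high edge set to zero (the zero-frequency term is
#' always removed); the inverse transform is returned. The filter is a
#' frequency-domain projection, hence idempotent.
#'
#' @param vol a [bold_volume].
#' @param band_hz length-2 passband in Hz; the high edge must stay below
#'   the Nyquist frequency 1/(2 TR).
#' @param mask a [brain_mask].
#' @return A [bold_volume]; out-of-mask voxels are zeroed.
#' @export
bandpass_ideal <- function(vol, band_hz, mask) {
  stopifnot(inherits(vol, "bold_volume"), length(band_hz) == 2L)
  lo <- band_hz[1]; hi <- band_hz[2]
  nyq <- 1 / (2 * vol$tr_seconds)
  if (!(0 < lo && lo < hi)) stop("band must satisfy 0 < low < high")
  if (hi >= nyq) stop(sprintf("band high %.4g Hz >= Nyquist %.4g Hz", hi, nyq))
  n <- vol$n_timepoints
  X <- vol_matrix(vol, mask)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / (n * vol$tr_seconds)
  keep <- f >= lo & f <= hi
  Fx <- stats::mvfft(X)
  Fx[!keep, ] <- 0
  out <- Re(stats::mvfft(Fx, inverse = TRUE)) / n
  matrix_to_vol(out, vol, mask)
}

#' Run the full per-subject preprocessing chain
#'
#' Discard initial volumes, then (under the default `"presmooth"` ordering)
#' smooth, detrend and band-pass filter. Under `"conventional"` ordering the
#' smoothing stage is deferred: the function returns both the unsmoothed
#' pipeline output (for homogeneity maps) and the smoothed one (for
#' connectivity).
#'
#' @param vol a [bold_volume] as acquired.
#' @param mask a [brain_mask].
#' @param cfg a [preprocess_config].
#' @return A list with elements `smoothed` and `unsmoothed` (both
#'   [bold_volume]s; `unsmoothed` is `NULL` under `"presmooth"` ordering).
#' @export
preprocess_subject <- function(vol, mask, cfg = preprocess_config()) {
  v <- discard_initial(vol, cfg$n_discard)
  if (cfg$stage_order == "presmooth") {
    v <- gaussian_smooth(v, cfg$fwhm_mm, mask)
    v <- detrend_linear(v, mask)
    v <- bandpass_ideal(v, cfg$band_hz, mask)
    list(smoothed = v, unsmoothed = NULL)
  } else {
    u <- detrend_linear(v, mask)
    u <- bandpass_ideal(u, cfg$band_hz, mask)
    s <- gaussian_smooth(v, cfg$fwhm_mm, mask)
    s <- detrend_linear(s, mask)
    s <- bandpass_ideal(s, cfg$band_hz, mask)
    list(smoothed = s, unsmoothed = u)
  }
}
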