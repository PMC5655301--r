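test_that("initial-volume discard keeps order and enforces length", {
  g <- tiny_grid(c(4L, 4L, 4L))
  vol <- noise_volume(g, nt = 140L)
  out <- discard_initial(vol, 5L)
  expect_equal(out$n_timepoints, 135L)
  expect_equal(out$values[, , , 1], vol$values[, , , 6])
  expect_equal(discard_initial(vol, 0L)$values, vol$values)
  short <- noise_volume(g, nt = 5L)
  expect_error(discard_initial(short, 5L), "discard")
})

test_that("motion QC applies per-axis 10 mm / 1 degree limits", {
  cfg <- preprocess_config()
  zero <- motion_trace(matrix(0, 10, 3), matrix(0, 10, 3))
  expect_true(qc_motion(zero, cfg)$pass)

  tr <- matrix(0, 10, 3); tr[7, 2] <- 12
  expect_false(qc_motion(motion_trace(tr, matrix(0, 10, 3)), cfg)$pass)

  # 0.0175 rad is 1.0027 degrees: just over the limit
  rot <- matrix(0, 10, 3); rot[3, 1] <- 0.0175
  v <- qc_motion(motion_trace(matrix(0, 10, 3), rot), cfg)
  expect_false(v$pass)
  expect_equal(v$max_rotation_deg, 0.0175 * 180 / pi)
  # just under stays in
  rot[3, 1] <- 0.017
  expect_true(qc_motion(motion_trace(matrix(0, 10, 3), rot), cfg)$pass)
})

test_that("Gaussian smoothing preserves constants and matches brute force", {
  g <- tiny_grid(c(9L, 9L, 9L), vox = 3)
  mask <- ellipsoid_mask(g, margin = 0.5)
  vol <- noise_volume(g, nt = 2L, seed = 3L)

  expect_equal(gaussian_smooth(vol, 0, mask)$values, vol$values)

  const <- constant_series_volume(g, c(7, 7), tr = 3)
  sm <- gaussian_smooth(const, 8, mask)
  expect_lt(max(abs(sm$values[, , , 1][mask$inside] - 7)), 1e-6)

  # unit impulse at an interior voxel vs direct convolution oracle
  arr <- array(0, g$dims); arr[5, 5, 5] <- 1
  imp <- bold_volume(array(arr, c(g$dims, 1)), g, 3)
  sm <- gaussian_smooth(imp, 8, mask)
  oracle <- brute_gaussian_smooth(arr, 8, 3, mask$inside)
  expect_equal(sm$values[, , , 1], oracle, tolerance = 1e-9)

  expect_error(gaussian_smooth(vol, -1, mask), "fwhm")
})

test_that("smoothing is mask-respecting: outside voxels never leak in", {
  g <- tiny_grid(c(9L, 9L, 9L), vox = 3)
  mask <- ellipsoid_mask(g, margin = 0.5)
  vol <- noise_volume(g, nt = 3L, seed = 5L)
  poisoned <- vol
  poisoned$values[rep(!mask$inside, 3L)] <- 1e6
  a <- gaussian_smooth(vol, 8, mask)
  b <- gaussian_smooth(poisoned, 8, mask)
  expect_equal(a$values[rep(mask$inside, 3L)], b$values[rep(mask$inside, 3L)],
               tolerance = 1e-9)
})

test_that("linear detrending removes exactly the least-squares line", {
  g <- tiny_grid(c(3L, 3L, 3L))
  mask <- full_mask(g)

  tt <- 1:10
  lin <- constant_series_volume(g, 2 + 3 * tt)
  out <- detrend_linear(lin, mask)
  expect_lt(max(abs(out$values)), 1e-9)

  # projection property: adding any line leaves residuals unchanged
  vol <- noise_volume(g, nt = 10L, seed = 7L)
  shifted <- vol
  line <- 5 - 0.7 * tt
  shifted$values <- vol$values + array(rep(line, each = prod(g$dims)),
                                       c(g$dims, 10L))
  expect_equal(detrend_linear(vol, mask)$values,
               detrend_linear(shifted, mask)$values, tolerance = 1e-9)

  # normal-equations oracle on [1, 2, 4]
  g1 <- image_grid(c(1, 1, 1), 3)
  v <- bold_volume(array(c(1, 2, 4), c(1, 1, 1, 3)), g1, 3)
  X <- cbind(1, 1:3)
  beta <- solve(t(X) %*% X, t(X) %*% c(1, 2, 4))
  oracle <- c(1, 2, 4) - X %*% beta
  expect_equal(as.numeric(detrend_linear(v, full_mask(g1))$values),
               as.numeric(oracle), tolerance = 1e-12)
})

test_that("ideal bandpass passes, rejects, and is an idempotent projection", {
  g <- image_grid(c(2, 2, 2), 3)
  mask <- full_mask(g)
  n <- 135; tr <- 3
  tt <- (0:(n - 1)) * tr

  inband <- constant_series_volume(g, sin(2 * pi * 0.05 * tt), tr = tr)
  out <- bandpass_ideal(inband, c(0.01, 0.08), mask)
  expect_gt(cor(out$values[1, 1, 1, ], inband$values[1, 1, 1, ]), 0.99)

  stopband <- constant_series_volume(g, sin(2 * pi * 0.12 * tt), tr = tr)
  out <- bandpass_ideal(stopband, c(0.01, 0.08), mask)
  expect_lt(var(out$values[1, 1, 1, ]) / var(stopband$values[1, 1, 1, ]), 0.01)

  vol <- noise_volume(g, nt = n, tr = tr, seed = 9L)
  once <- bandpass_ideal(vol, c(0.01, 0.08), mask)
  twice <- bandpass_ideal(once, c(0.01, 0.08), mask)
  expect_equal(twice$values, once$values, tolerance = 1e-9)

  # output orthogonal to an exact out-of-band frequency bin
  k_out <- 50  # f = 50/405 = 0.1235 Hz > 0.08
  probe <- sin(2 * pi * k_out * (0:(n - 1)) / n)
  y <- once$values[1, 1, 1, ]
  expect_lt(abs(sum(probe * y)), 1e-6 * sqrt(sum(probe^2) * sum(y^2)))

  expect_error(bandpass_ideal(vol, c(0.01, 0.2), mask), "Nyquist")
  expect_error(bandpass_ideal(vol, c(0.08, 0.01), mask), "low < high")
})

test_that("default stage order composes smooth, detrend, bandpass", {
  g <- tiny_grid(c(7L, 7L, 7L), vox = 3)
  mask <- ellipsoid_mask(g, margin = 0.5)
  vol <- noise_volume(g, nt = 20L, tr = 3, seed = 13L)
  cfg <- preprocess_config(n_discard = 2L, fwhm_mm = 6, band_hz = c(0.01, 0.08))
  pp <- preprocess_subject(vol, mask, cfg)
  manual <- bandpass_ideal(
    detrend_linear(gaussian_smooth(discard_initial(vol, 2L), 6, mask), mask),
    c(0.01, 0.08), mask)
  expect_equal(pp$smoothed$values, manual$values, tolerance = 1e-12)
  expect_null(pp$unsmoothed)

  cfg2 <- preprocess_config(n_discard = 2L, fwhm_mm = 6,
                            stage_order = "conventional")
  pp2 <- preprocess_subject(vol, mask, cfg2)
  expect_false(is.null(pp2$unsmoothed))
})
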