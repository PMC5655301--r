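mask1 <- function() full_mask(image_grid(c(1L, 1L, 1L), 3))

maps_from <- function(values_per_subject, mask = mask1()) {
  lapply(values_per_subject, function(v)
    stat_map(array(v, mask$grid$dims), mask, "z"))
}

test_that("one-sample t matches direct arithmetic and flags degeneracy", {
  m <- maps_from(list(1, 2, 3))
  t1 <- one_sample_t(m)
  expect_equal(map_values(t1), 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(t1$meta$df, 2L)

  sym <- one_sample_t(maps_from(list(-2, -1, 1, 2)))
  expect_equal(map_values(sym), 0)

  zero <- one_sample_t(maps_from(list(0, 0, 0)))
  expect_equal(map_values(zero), 0)
  expect_equal(zero$meta$degenerate_voxels, 1L)
})

test_that("two-sample pooled t matches the textbook oracle and antisymmetry", {
  a <- maps_from(list(1, 2, 3)); b <- maps_from(list(2, 3, 4))
  t2 <- two_sample_t(a, b)
  # pooled oracle: s2p = 1, se = sqrt(2/3)
  expect_equal(map_values(t2), -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(map_values(t2), -1.2247, tolerance = 1e-4)
  expect_equal(t2$meta$df, 4L)

  expect_equal(map_values(two_sample_t(b, a)), -map_values(t2),
               tolerance = 1e-15)
  expect_equal(map_values(two_sample_t(a, a)), 0)

  # oracle equivalence with stats::t.test on random small inputs
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    tt <- two_sample_t(maps_from(as.list(x)), maps_from(as.list(y)))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(map_values(tt), unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("t to p and z conversions are monotone, symmetric and match", {
  df <- 4
  m <- full_mask(image_grid(c(5L, 1L, 1L), 3))
  tvals <- c(-3, -1.2247, 0, 1.2247, 6)
  tmap <- stat_map(array(tvals, c(5, 1, 1)), m, "t", meta = list(df = df))
  p <- map_values(t_to_p(tmap))
  expect_equal(p[3], 1)
  expect_equal(p[4], 0.2879, tolerance = 1e-3)   # numeric-integration oracle
  expect_equal(p[2], p[4], tolerance = 1e-12)
  expect_true(all(diff(p[3:5]) < 0))             # larger |t| -> smaller p

  z <- map_values(t_to_z(tmap))
  expect_equal(z[3], 0)
  expect_equal(z[2], -z[4], tolerance = 1e-12)   # odd symmetry in t
  expect_equal(t_to_z(-2.5, df = 4), -t_to_z(2.5, df = 4), tolerance = 1e-12)
  # probability matching: one-tailed normal area equals one-tailed t area
  expect_equal(pnorm(t_to_z(1.7, df = 9)), pt(1.7, 9), tolerance = 1e-10)
  # large |t| does not overflow to Inf
  expect_true(is.finite(t_to_z(60, df = 120)))
  expect_error(t_to_p(tmap, df = 0), "df")
})

test_that("cluster thresholding applies the strict extent rule", {
  g <- image_grid(c(30L, 10L, 10L), 3)
  mask <- full_mask(g)
  tv <- array(0, g$dims)
  # suprathreshold blobs of 51 and 49 voxels (df = 40, crit ~ 3.55)
  blob1 <- arrayInd(1:51, c(6, 10, 10))          # 51 voxels in a 6x10x10 corner
  tv[cbind(blob1[, 1], blob1[, 2], blob1[, 3])] <- 10
  blob2 <- arrayInd(1:49, c(5, 10, 10))
  tv[cbind(blob2[, 1] + 20L, blob2[, 2], blob2[, 3])] <- 10
  tmap <- stat_map(tv, mask, "t", meta = list(df = 40L))
  rec <- threshold_clusters(tmap, p_thresh = 0.001, extent = 50L)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$cluster_size_voxels, 51L)
  expect_equal(rec$sign, "increase")

  # empty suprathreshold set
  expect_equal(nrow(threshold_clusters(stat_map(array(0, g$dims), mask, "t",
                                                meta = list(df = 40L)))), 0L)
})

test_that("connectivity controls whether corner-touching blobs merge", {
  g <- image_grid(c(12L, 12L, 12L), 3)
  mask <- full_mask(g)
  tv <- array(0, g$dims)
  tv[1:3, 1:5, 1:2] <- 8          # 30 voxels
  tv[4:6, 6:10, 3:4] <- 8         # 30 voxels, touching only at corner (3,5,2)-(4,6,3)
  tmap <- stat_map(tv, mask, "t", meta = list(df = 40L))
  rec26 <- threshold_clusters(tmap, extent = 50L, connectivity = 26L)
  expect_equal(rec26$cluster_size_voxels, 60L)
  rec6 <- threshold_clusters(tmap, extent = 50L, connectivity = 6L)
  expect_equal(nrow(rec6), 0L)
  rec6b <- threshold_clusters(tmap, extent = 20L, connectivity = 6L)
  expect_equal(sort(rec6b$cluster_size_voxels), c(30L, 30L))

  # label_components oracle on the same lattice
  lab <- restfmri:::label_components(tv > 0, 6L)
  expect_equal(max(lab), 2L)
  lab26 <- restfmri:::label_components(tv > 0, 26L)
  expect_equal(max(lab26), 1L)
})

test_that("thresholding is monotone in extent and p threshold", {
  set.seed(23)
  g <- image_grid(c(14L, 14L, 14L), 3)
  mask <- ellipsoid_mask(g, margin = 0.5)
  tv <- array(0, g$dims)
  tv[mask$inside] <- rnorm(sum(mask$inside), sd = 3)
  tmap <- stat_map(tv, mask, "t", meta = list(df = 30L))
  n_base <- nrow(threshold_clusters(tmap, p_thresh = 0.05, extent = 2L))
  expect_gte(n_base, nrow(threshold_clusters(tmap, p_thresh = 0.05, extent = 5L)))
  expect_gte(n_base, nrow(threshold_clusters(tmap, p_thresh = 0.01, extent = 2L)))
})

test_that("cluster report mirrors the peak-table layout", {
  g <- image_grid(c(40L, 10L, 10L), 3, origin_mm = c(-60, -15, -15))
  mask <- full_mask(g)
  tv <- array(0, g$dims)
  tv[1:4, 1:4, 1:4] <- -9        # left hemisphere decrease, peak near x=-57
  tv[2, 2, 2] <- -12
  tv[32:36, 1:4, 1:4] <- 9       # right hemisphere increase
  tv[33, 2, 2] <- 11
  tmap <- stat_map(tv, mask, "t", meta = list(df = 124L))
  rec <- threshold_clusters(tmap, extent = 10L)
  tab <- cluster_report(rec, contrast = "demo")
  expect_equal(names(tab)[1:8],
               c("cluster_size", "hemisphere", "sign", "peak_T", "peak_Z",
                 "x", "y", "z"))
  expect_equal(tab$hemisphere[tab$sign == "decrease"], "L")
  expect_equal(tab$hemisphere[tab$sign == "increase"], "R")
  expect_true(all(diff(tab$cluster_size) <= 0))
  expect_equal(tab$x[tab$sign == "decrease"], -57)
  expect_equal(tab$anatomical_label, c("", ""))

  empty <- cluster_report(threshold_clusters(
    stat_map(array(0, g$dims), mask, "t", meta = list(df = 10L))))
  expect_equal(nrow(empty), 0L)
  expect_true("peak_Z" %in% names(empty))
})

test_that("dice overlap behaves on edge cases", {
  expect_equal(dice_overlap(1:10, 6:15), 2 * 5 / 20)
  expect_equal(dice_overlap(integer(), integer()), 0)
  expect_equal(dice_overlap(1:5, 1:5), 1)
})
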