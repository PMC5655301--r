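#' Rank a time series
#'
#' Ranks 1..n with ties receiving the average of the ranks they cover.
#' Exact ties are measure-zero for continuous BOLD data, so no tie
#' correction is applied in the concordance denominator (documented
#' limitation).
#'
#' @param series numeric vector, length >= 2, finite.
#' @return Numeric vector of ranks summing to n(n+1)/2.
#' @export
rank_timeseries <- function(series) {
  if (length(series) < 2L) stop("series must have length >= 2")
  if (!all(is.finite(series))) stop("series must be finite")
  rank(series, ties.method = "average")
}

#' Kendall's coefficient of concordance
#'
#' For K ranked series over n timepoints, with Ri the across-series rank
#' sum at timepoint i and Rbar = (n+1) K / 2 its mean,
#' \deqn{W = \frac{\sum_i R_i^2 - n \bar R^2}{\tfrac{1}{12} K^2 (n^3 - n)}.}
#' W lies in [0, 1]: 1 for identical rankings, 0 for perfectly cancelling
#' ones, and E[W] = 1/K for independent series. K (n-1) W is the Friedman
#' chi-square statistic on the same ranks.
#'
#' @param ranks a K x n matrix of ranks, one series per row (e.g. rows from
#'   [rank_timeseries]).
#' @return W, clamped to [0, 1] only against floating slop (<= 1e-12).
#' @export
kendall_w <- function(ranks) {
  ranks <- as.matrix(ranks)
  K <- nrow(ranks); n <- ncol(ranks)
  if (K < 2L || n < 2L) stop("kendall_w needs K >= 2 series and n >= 2 timepoints")
  Ri <- colSums(ranks)
  Rbar <- (n + 1) * K / 2
  W <- (sum(Ri^2) - n * Rbar^2) / (K^2 * (n^3 - n) / 12)
  min(max(W, 0), 1)
}

# relative (dx,dy,dz) offsets of the cubic neighbourhoods: 7 = faces,
# 19 = faces + edges, 27 = full cube, each including the centre voxel
neighborhood_offsets <- function(neighborhood = 27L) {
  if (!neighborhood %in% c(7L, 19L, 27L))
    stop("neighborhood must be one of 7, 19, 27")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "7" = ord <= 1, "19" = ord <= 2, "27" = rep(TRUE, 27))
  as.matrix(g[keep, , drop = FALSE])
}

# add `src` shifted by (dx,dy,dz) into `acc` (both (nx,ny,nz,nt) arrays),
# zero-padding at the grid edges
shift_add <- function(acc, src, off) {
  d <- dim(src)
  sx <- max(1L, 1L + off[1]):min(d[1], d[1] + off[1])
  sy <- max(1L, 1L + off[2]):min(d[2], d[2] + off[2])
  sz <- max(1L, 1L + off[3]):min(d[3], d[3] + off[3])
  acc[sx, sy, sz, ] <- acc[sx, sy, sz, , drop = FALSE] +
    src[sx - off[1], sy - off[2], sz - off[3], , drop = FALSE]
  acc
}

#' Regional homogeneity map
#'
#' Kendall's W of each in-mask voxel's time series with its in-mask
#' neighbours from the chosen cubic neighbourhood (default 27: the voxel and
#' its 26 adjacent voxels). Neighbourhoods are truncated at the mask
#' boundary — the effective K is the count of in-mask neighbourhood voxels —
#' so the map's support equals the mask; voxels with effective K < 2 get
#' W = 0 and are flagged in `meta$low_k`.
#'
#' @param vol a preprocessed [bold_volume].
#' @param mask a [brain_mask] on the same grid.
#' @param neighborhood 7, 19 or 27 (default).
#' @return A [stat_map] of kind `"W"` with `meta$neighborhood`, `meta$n`,
#'   `meta$effective_k` (3D array) and `meta$low_k` flags.
#' @export
reho_map <- function(vol, mask, neighborhood = 27L) {
  stopifnot(inherits(vol, "bold_volume"), inherits(mask, "brain_mask"))
  if (!same_grid(vol$grid, mask$grid)) stop("volume and mask grids differ")
  n <- vol$n_timepoints
  if (n < 2L) stop("need at least 2 timepoints")
  offs <- neighborhood_offsets(neighborhood)
  d <- vol$grid$dims

  X <- vol_matrix(vol, mask)                       # time x voxels
  R <- apply(X, 2L, rank, ties.method = "average") # time x voxels
  rk <- array(0, dim = c(d, n))
  flat <- matrix(rk, nrow = prod(d))
  flat[which(mask$inside), ] <- t(R)
  rk <- array(flat, dim = c(d, n))
  mk <- array(0, dim = c(d, 1L))
  mk[, , , 1L] <- as.numeric(mask$inside)

  rsum <- array(0, dim = c(d, n))
  ksum <- array(0, dim = c(d, 1L))
  for (i in seq_len(nrow(offs))) {
    rsum <- shift_add(rsum, rk, offs[i, ])
    ksum <- shift_add(ksum, mk, offs[i, ])
  }
  K <- ksum[, , , 1L]
  # sum over timepoints of (Ri - K (n+1)/2)^2, per voxel
  dev <- rsum - array(rep(K, n) * (n + 1) / 2, dim = c(d, n))
  S <- rowSums(matrix(dev^2, nrow = prod(d)))
  W <- array(0, dim = d)
  ok <- mask$inside & K >= 2
  W[ok] <- 12 * S[ok] / (K[ok]^2 * (n^3 - n))
  W[W < 0] <- 0
  W[W > 1] <- 1
  stat_map(W, mask, "W",
           meta = list(neighborhood = neighborhood, n = n,
                       effective_k = K * mask$inside,
                       low_k = mask$inside & K < 2))
}
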