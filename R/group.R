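# stack a list of stat_maps (common grid/mask) into a voxels x subjects matrix
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 2L)
  mask <- maps[[1L]]$mask
  for (m in maps[-1L])
    if (!same_grid(m$grid, mask$grid) ||
        !identical(m$mask$inside, mask$inside))
      stop("all maps must share one grid and mask")
  nv <- sum(mask$inside)
  vals <- vapply(maps, map_values, numeric(nv))
  if (is.null(dim(vals))) dim(vals) <- c(nv, length(maps))
  list(values = vals, mask = mask)
}

#' One-sample voxelwise t-map
#'
#' Per voxel, t = mean / (sd / sqrt(m)) across the m subject maps, with the
#' (m-1)-denominator sample standard deviation; df = m - 1. Voxels with
#' zero variance get t = 0 and are flagged in `meta$degenerate_voxels`.
#'
#' @param maps list of subject [stat_map]s on one grid/mask.
#' @return A [stat_map] of kind `"t"` with `meta$df`.
#' @export
one_sample_t <- function(maps) {
  st <- stack_maps(maps)
  m <- ncol(st$values)
  mu <- rowMeans(st$values)
  sd <- sqrt(rowSums((st$values - mu)^2) / (m - 1))
  t <- ifelse(sd > 0, mu / (sd / sqrt(m)), 0)
  out <- array(0, dim = st$mask$grid$dims)
  out[st$mask$inside] <- t
  stat_map(out, st$mask, "t",
           meta = list(df = m - 1L, contrast = "one_sample",
                       degenerate_voxels = which(sd == 0)))
}

#' Two-sample voxelwise t-map (pooled variance)
#'
#' Equal-variance Student t per voxel with sign convention a - b, so with
#' patients as group a a decrease in patients is negative;
#' df = n_a + n_b - 2. Voxels with zero pooled variance get t = 0 and are
#' flagged.
#'
#' @param maps_a,maps_b lists of subject [stat_map]s (each of length >= 2)
#'   on one common grid/mask.
#' @return A [stat_map] of kind `"t"` with `meta$df`.
#' @export
two_sample_t <- function(maps_a, maps_b) {
  stopifnot(length(maps_a) >= 2L, length(maps_b) >= 2L)
  st <- stack_maps(c(maps_a, maps_b))
  na <- length(maps_a); nb <- length(maps_b)
  A <- st$values[, seq_len(na), drop = FALSE]
  B <- st$values[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, (ma - mb) / se, 0)
  out <- array(0, dim = st$mask$grid$dims)
  out[st$mask$inside] <- t
  stat_map(out, st$mask, "t",
           meta = list(df = df, n_a = na, n_b = nb, contrast = "a_minus_b",
                       degenerate_voxels = which(se == 0)))
}

#' Convert a t-map to two-tailed p-values
#'
#' @param t_map a [stat_map] of kind `"t"`.
#' @param df degrees of freedom (defaults to `t_map$meta$df`).
#' @return A [stat_map] of kind `"p"`; out-of-mask voxels hold 0.
#' @export
t_to_p <- function(t_map, df = t_map$meta$df) {
  stopifnot(identical(t_map$kind, "t"))
  if (is.null(df) || df < 1) stop("df must be >= 1")
  t <- map_values(t_map)
  p <- 2 * stats::pt(-abs(t), df)
  out <- array(0, dim = t_map$mask$grid$dims)
  out[t_map$mask$inside] <- p
  stat_map(out, t_map$mask, "p", meta = t_map$meta)
}

#' Convert a t-map to equivalent normal z-scores
#'
#' Sign-preserving probability matching: z is the standard-normal quantile
#' whose one-tailed probability equals the Student one-tailed probability
#' of t. Computed on the log scale through complementary tails so large
#' |t| does not underflow.
#'
#' @param t_map a [stat_map] of kind `"t"`, or a bare numeric vector
#'   (then `df` is required).
#' @param df degrees of freedom.
#' @return A [stat_map] of kind `"z"` (or numeric vector for vector input).
#' @export
t_to_z <- function(t_map, df = NULL) {
  vec_in <- is.numeric(t_map)
  t <- if (vec_in) t_map else {
    stopifnot(identical(t_map$kind, "t"))
    if (is.null(df)) df <- t_map$meta$df
    map_values(t_map)
  }
  if (is.null(df) || df < 1) stop("df must be >= 1")
  logp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z <- sign(t) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  if (vec_in) return(z)
  out <- array(0, dim = t_map$mask$grid$dims)
  out[t_map$mask$inside] <- z
  stat_map(out, t_map$mask, "z", meta = t_map$meta)
}

# connected-component labelling of a logical 3D array under 6/18/26
# connectivity; returns an integer array of labels (0 = background)
label_components <- function(sel, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  nb <- switch(as.character(connectivity), "6" = 7L, "18" = 19L, "26" = 27L)
  offs <- neighborhood_offsets(nb)
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  d <- dim(sel)
  lab <- array(0L, dim = d)
  idx <- which(sel)
  if (!length(idx)) return(lab)
  coords <- arrayInd(idx, d)
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      ci <- arrayInd(v, d)
      for (j in seq_len(nrow(offs))) {
        x <- ci[1] + offs[j, 1]; y <- ci[2] + offs[j, 2]; z <- ci[3] + offs[j, 3]
        if (x < 1L || y < 1L || z < 1L || x > d[1] || y > d[2] || z > d[3])
          next
        w <- v + lin_off[j]
        if (sel[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' Cluster-extent thresholding of a t-map
#'
#' Voxels with two-tailed p below `p_thresh` are split by t sign; connected
#' components are labelled under the chosen connectivity; components with
#' strictly more than `extent` voxels are retained (a "> 50 voxels" rule is
#' strict: 51 is the minimum reported size). Each surviving cluster is
#' summarised by its maximal-|t| voxel. This is uncorrected cluster-extent
#' inference: no familywise error control beyond the extent heuristic.
#'
#' @param t_map a [stat_map] of kind `"t"`.
#' @param df degrees of freedom (defaults to `t_map$meta$df`).
#' @param p_thresh voxelwise two-tailed p threshold (default 0.001).
#' @param extent minimum cluster size, exclusive (default 50).
#' @param connectivity 6, 18 or 26 (default: corner-touching voxels
#'   connect).
#' @param sign `"both"` (default), `"increase"` (t > 0) or `"decrease"`.
#' @return A data.frame of cluster records: `cluster_size_voxels`, `sign`,
#'   `peak_t`, `peak_z`, `peak_x/y/z` (mm), `hemisphere`, plus a `voxels`
#'   list-column of linear voxel indices; sorted by size descending.
#' @export
threshold_clusters <- function(t_map, df = t_map$meta$df, p_thresh = 0.001,
                               extent = 50L, connectivity = 26L,
                               sign = c("both", "increase", "decrease")) {
  sign <- match.arg(sign)
  stopifnot(p_thresh > 0, extent >= 0)
  tv <- t_map$values
  crit <- stats::qt(1 - p_thresh / 2, df)      # |t| > crit  <=>  p < p_thresh
  rec <- list()
  dirs <- switch(sign, both = c("increase", "decrease"),
                 increase = "increase", decrease = "decrease")
  for (dr in dirs) {
    sel <- t_map$mask$inside &
      (if (dr == "increase") tv > crit else tv < -crit)
    lab <- label_components(sel, connectivity)
    if (!max(lab)) next
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      if (length(vox) <= extent) next
      peak <- vox[which.max(abs(tv[vox]))]
      pk_t <- tv[peak]
      pk_mm <- voxel_to_mm(t_map$grid, arrayInd(peak, dim(tv)) - 1L)
      rec[[length(rec) + 1L]] <- data.frame(
        cluster_size_voxels = length(vox), sign = dr,
        peak_t = pk_t, peak_z = t_to_z(pk_t, df),
        peak_x = pk_mm[1], peak_y = pk_mm[2], peak_z_mm = pk_mm[3],
        hemisphere = if (pk_mm[1] < 0) "L" else if (pk_mm[1] > 0) "R" else "midline",
        stringsAsFactors = FALSE)
      rec[[length(rec)]]$voxels <- list(vox)
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(cluster_size_voxels = integer(), sign = character(),
               peak_t = numeric(), peak_z = numeric(), peak_x = numeric(),
               peak_y = numeric(), peak_z_mm = numeric(),
               hemisphere = character(), voxels = I(list()),
               stringsAsFactors = FALSE)
  out[order(-out$cluster_size_voxels), , drop = FALSE]
}

#' Format cluster records as a peak table
#'
#' Columns mirror the classic neuroimaging results table: cluster size in
#' voxels, hemisphere (from the sign of the peak x coordinate), peak T and
#' equivalent Z, peak mm coordinates, and a free-text anatomical label left
#' blank (no atlas lookup is performed).
#'
#' @param records cluster records from [threshold_clusters()].
#' @param contrast free-text contrast description stored in the table.
#' @param path optional TSV output path.
#' @return A data.frame (invisibly also written to `path` when given).
#' @export
cluster_report <- function(records, contrast = "", path = NULL) {
  tab <- data.frame(
    cluster_size = records$cluster_size_voxels,
    hemisphere = records$hemisphere,
    sign = records$sign,
    peak_T = round(records$peak_t, 2),
    peak_Z = round(records$peak_z, 2),
    x = records$peak_x, y = records$peak_y, z = records$peak_z_mm,
    anatomical_label = rep("", nrow(records)),
    contrast = rep(contrast, nrow(records)),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$cluster_size), , drop = FALSE]
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

#' Dice overlap between a set of cluster voxels and a reference voxel set
#'
#' @param voxels integer vector of linear voxel indices (e.g. the union of
#'   `voxels` entries of cluster records).
#' @param reference integer vector of linear voxel indices.
#' @return 2|A n B| / (|A| + |B|); 0 when both are empty.
#' @export
dice_overlap <- function(voxels, reference) {
  voxels <- unique(voxels); reference <- unique(reference)
  if (!length(voxels) && !length(reference)) return(0)
  2 * length(intersect(voxels, reference)) /
    (length(voxels) + length(reference))
}

#' Component-wise cluster recovery score
#'
#' For each ground-truth component (e.g. one implanted effect sphere),
#' finds the reported cluster with the highest Dice overlap and averages
#' these best-pair Dice values over components. A component no cluster
#' touches contributes 0, so missed effects pull the score down, while a
#' genuine detection elsewhere does not.
#'
#' @param records cluster records from [threshold_clusters()] (typically
#'   filtered to one sign).
#' @param components list of integer vectors of linear voxel indices, one
#'   per implanted effect region.
#' @return Mean over components of the best-matching cluster's Dice.
#' @export
recovery_dice <- function(records, components) {
  if (!length(components)) return(0)
  mean(vapply(components, function(comp) {
    if (nrow(records) == 0L) return(0)
    max(vapply(records$voxels, dice_overlap, numeric(1), reference = comp))
  }, numeric(1)))
}
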