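#' Synthetic cohort specification
#'
#' Describes a two-group resting-state BOLD cohort with implanted,
#' recoverable group effects. Every voxel's series is
#' baseline + drift + coupling x shared network signal (inside the DMN
#' spheres) + weight x ROI-common local signal (inside the homogeneity
#' spheres) + white noise; both structured signals are band-limited to the
#' analysis band (0.01-0.08 Hz) with the same ideal filter preprocessing
#' applies, so the implanted structure survives filtering. "Patients" get
#' weaker network coupling and weaker local synchrony than "controls",
#' mirroring a decreased-connectivity / decreased-homogeneity phenotype.
#'
#' The default grid is a desk-scale 24 x 28 x 24 lattice at 3 mm with an
#' ellipsoidal brain mask, positioned so the precuneus seed at
#' (-12, -47, 32) mm sits on a voxel centre; full MNI-size grids are
#' supported but not the default. The default cohort is 20 patients vs
#' 20 controls with no motion outliers (the recovery-experiment
#' configuration); motion outliers and study-scale cohorts are requested
#' explicitly.
#'
#' @param n_patients,n_controls group sizes (>= 1).
#' @param grid an [image_grid].
#' @param n_timepoints_acquired acquired series length (before any
#'   discard), default 140.
#' @param tr_seconds repetition time, default 3.0 s.
#' @param seed_center_mm DMN seed centre, default (-12, -47, 32).
#' @param dmn_rois list of `list(center_mm=, radius_mm=)` spheres carrying
#'   the shared network signal; defaults to the seed sphere plus one
#'   posterior parietal target sphere.
#' @param fc_coupling_controls,fc_coupling_patients shared-signal coupling
#'   per group, in [0, 1]; patients must not exceed controls when
#'   simulating the decreased direction.
#' @param reho_local_weight_controls,reho_local_weight_patients ROI-common
#'   local-signal weight per group.
#' @param reho_effect_rois list of spheres carrying the local-synchrony
#'   signal.
#' @param subject_effect_sd between-subject sd of the coupling and of the
#'   local weight (each subject's values are drawn around the group mean
#'   and truncated to [0, 1]). Real cohorts vary in connectivity strength
#'   from person to person; without this term the group t statistic is
#'   driven by estimation noise alone and reaches unrealistic magnitudes.
#' @param background_coupling_sd sd of a per-subject, brain-wide coupling
#'   to the network signal (mean 0, identical in both groups). Emulates
#'   global connectivity fluctuations, giving the z maps realistic
#'   between-subject variance outside the effect regions so group t maps
#'   do not spread artificially beyond the implanted support.
#' @param local_mixing_mean,local_mixing_sd per-subject weight with which
#'   each voxel's noise is mixed with its 6-neighbour mean (truncated at
#'   0). Emulates subject-varying intrinsic spatial smoothness, the
#'   between-subject variance floor of neighbourhood-concordance maps.
#' @param drift_slope_sd sd of the per-voxel linear drift slope, signal
#'   units per timepoint.
#' @param noise_sd white-noise sd (> 0).
#' @param baseline constant added to every series (removed by detrending).
#' @param n_motion_outliers integer pair (patients, controls): how many
#'   traces per group must violate the motion QC limits.
#' @param age_mean,age_sd length-2 (patients, controls) demographic
#'   parameters.
#' @param rng_seed integer master seed; identical specs generate identical
#'   cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20L, n_controls = 20L,
                        grid = default_grid(),
                        n_timepoints_acquired = 140L, tr_seconds = 3.0,
                        seed_center_mm = c(-12, -47, 32),
                        dmn_rois = list(
                          list(center_mm = c(-12, -47, 32), radius_mm = 10),
                          list(center_mm = c(9, -71, 35), radius_mm = 10)),
                        fc_coupling_controls = 0.8,
                        fc_coupling_patients = 0.35,
                        reho_local_weight_controls = 0.90,
                        reho_local_weight_patients = 0.45,
                        reho_effect_rois = list(
                          list(center_mm = c(6, -27, 42), radius_mm = 10)),
                        subject_effect_sd = 0.12,
                        background_coupling_sd = 0.10,
                        local_mixing_mean = 0.15, local_mixing_sd = 0.05,
                        drift_slope_sd = 0.01, noise_sd = 1.0,
                        baseline = 100,
                        n_motion_outliers = c(0L, 0L),
                        age_mean = c(27.9, 29.1), age_sd = c(8.3, 7.5),
                        rng_seed = 20170828L) {
  stopifnot(n_patients >= 1L, n_controls >= 1L, inherits(grid, "image_grid"),
            n_timepoints_acquired >= 2L, tr_seconds > 0, noise_sd > 0,
            drift_slope_sd >= 0)
  cpl <- c(fc_coupling_controls, fc_coupling_patients,
           reho_local_weight_controls, reho_local_weight_patients)
  if (any(cpl < 0) || any(cpl > 1))
    stop("coupling and local weights must lie in [0, 1]")
  if (fc_coupling_patients > fc_coupling_controls ||
      reho_local_weight_patients > reho_local_weight_controls)
    stop("patients' coupling/weight must not exceed controls' (decreased direction)")
  n_motion_outliers <- rep_len(as.integer(n_motion_outliers), 2L)
  if (any(n_motion_outliers < 0) || n_motion_outliers[1] > n_patients ||
      n_motion_outliers[2] > n_controls)
    stop("n_motion_outliers must fit within the group sizes")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    grid = grid, n_timepoints_acquired = as.integer(n_timepoints_acquired),
    tr_seconds = tr_seconds, seed_center_mm = as.numeric(seed_center_mm),
    dmn_rois = dmn_rois,
    fc_coupling_controls = fc_coupling_controls,
    fc_coupling_patients = fc_coupling_patients,
    reho_local_weight_controls = reho_local_weight_controls,
    reho_local_weight_patients = reho_local_weight_patients,
    reho_effect_rois = reho_effect_rois,
    subject_effect_sd = subject_effect_sd,
    background_coupling_sd = background_coupling_sd,
    local_mixing_mean = local_mixing_mean, local_mixing_sd = local_mixing_sd,
    drift_slope_sd = drift_slope_sd, noise_sd = noise_sd,
    baseline = baseline, n_motion_outliers = n_motion_outliers,
    age_mean = age_mean, age_sd = age_sd,
    rng_seed = as.integer(rng_seed)), class = "cohort_spec")
}

#' Default desk-scale grid
#'
#' 24 x 28 x 24 voxels at 3 mm, origin (-36, -89, -4) mm, so coordinates
#' span roughly the MNI brain envelope and the default seed centre falls on
#' a voxel centre.
#' @return An [image_grid].
#' @export
default_grid <- function() {
  image_grid(c(24L, 28L, 24L), c(3, 3, 3), origin_mm = c(-36, -89, -4))
}

#' Brain mask used by the synthetic generator
#' @param spec a [cohort_spec].
#' @return The [ellipsoid_mask] on the spec grid.
#' @export
cohort_mask <- function(spec) ellipsoid_mask(spec$grid, margin = 1)

# unit-variance band-limited signal: ideal-bandpass-filtered white noise,
# same frequency mask the preprocessing filter uses
bandlimited_signal <- function(n, tr, band = c(0.01, 0.08)) {
  x <- stats::rnorm(n)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / (n * tr)
  Fx <- stats::fft(x)
  Fx[!(f >= band[1] & f <= band[2])] <- 0
  y <- Re(stats::fft(Fx, inverse = TRUE)) / n
  y / stats::sd(y)
}

roi_voxel_indices <- function(grid, roi, brain) {
  m <- sphere_mask(grid, roi$center_mm, roi$radius_mm, brain)
  which(m$inside)
}

# smooth random-walk motion trace; the walk's largest per-axis excursion is
# scaled to exactly max_trans_mm / max_rot_deg (the per-axis peaks below the
# overall peak stay random)
motion_walk <- function(n, max_trans_mm, max_rot_deg) {
  walk3 <- function(target) {
    w <- vapply(1:3, function(i) cumsum(stats::rnorm(n)), numeric(n))
    w * (target / max(abs(w)))
  }
  motion_trace(walk3(max_trans_mm), walk3(max_rot_deg * pi / 180))
}

#' Generate one synthetic subject
#'
#' Deterministic given `subject_seed`: the same spec, group and seed yield
#' bit-identical output.
#'
#' @param spec a [cohort_spec].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed integer RNG seed for this subject.
#' @param motion_outlier when `TRUE` the motion trace is scaled to violate
#'   the default QC limits (peak translation 11-15 mm); otherwise it stays
#'   well inside them (peak 0.3-2 mm, 0.05-0.5 degrees).
#' @return A list with `volume` (a [bold_volume]) and `motion`
#'   (a [motion_trace]).
#' @export
generate_subject <- function(spec, group = c("patient", "control"),
                             subject_seed = 1L, motion_outlier = FALSE) {
  group <- match.arg(group)
  set.seed(subject_seed)
  grid <- spec$grid
  brain <- cohort_mask(spec)
  nt <- spec$n_timepoints_acquired
  nvox <- prod(grid$dims)

  jitter <- function(mu) min(max(stats::rnorm(1, mu, spec$subject_effect_sd),
                                 0), 1)
  coupling <- jitter(if (group == "patient") spec$fc_coupling_patients else
    spec$fc_coupling_controls)
  weight <- jitter(if (group == "patient") spec$reho_local_weight_patients else
    spec$reho_local_weight_controls)

  vals <- matrix(stats::rnorm(nvox * nt, sd = spec$noise_sd), nvox, nt)

  # subject-specific intrinsic smoothness: mix each voxel's noise with the
  # mean of its 6 face neighbours
  mix <- max(stats::rnorm(1, spec$local_mixing_mean, spec$local_mixing_sd), 0)
  if (mix > 0) {
    arr <- array(vals, c(grid$dims, nt))
    nb <- array(0, c(grid$dims, nt))
    cnt <- array(0, c(grid$dims, 1L))
    one <- array(1, c(grid$dims, 1L))
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      nb <- shift_add(nb, arr, off)
      cnt <- shift_add(cnt, one, off)
    }
    nb <- nb / as.numeric(cnt)            # recycled over timepoints
    vals <- (1 - mix) * vals + mix * matrix(nb, nvox, nt)
  }

  slope <- stats::rnorm(nvox, sd = spec$drift_slope_sd)
  vals <- vals + outer(slope, seq_len(nt) - (nt + 1) / 2) + spec$baseline

  s_dmn <- bandlimited_signal(nt, spec$tr_seconds)
  # brain-wide subject-level coupling fluctuation, mean zero in both groups
  bg <- stats::rnorm(1, 0, spec$background_coupling_sd)
  if (bg != 0) {
    bvox <- which(brain$inside)
    vals[bvox, ] <- vals[bvox, ] + bg *
      matrix(s_dmn, length(bvox), nt, byrow = TRUE)
  }
  for (roi in spec$dmn_rois) {
    vox <- roi_voxel_indices(grid, roi, brain)
    vals[vox, ] <- vals[vox, ] + coupling *
      matrix(s_dmn, length(vox), nt, byrow = TRUE)
  }
  for (roi in spec$reho_effect_rois) {
    u <- bandlimited_signal(nt, spec$tr_seconds)
    vox <- roi_voxel_indices(grid, roi, brain)
    vals[vox, ] <- vals[vox, ] + weight *
      matrix(u, length(vox), nt, byrow = TRUE)
  }
  vals[!brain$inside, ] <- 0

  motion <- if (motion_outlier)
    motion_walk(nt, stats::runif(1, 11, 15), stats::runif(1, 0.3, 0.8))
  else
    motion_walk(nt, stats::runif(1, 0.3, 2), stats::runif(1, 0.05, 0.5))

  list(volume = bold_volume(array(vals, dim = c(grid$dims, nt)), grid,
                            spec$tr_seconds),
       motion = motion)
}

#' Ground-truth effect locations of a cohort spec
#'
#' `fc_effect_voxels` are the DMN sphere voxels (where seed coupling
#' differs between groups); `reho_effect_voxels` are the local-synchrony
#' sphere voxels. The per-sphere voxel sets are returned as components for
#' component-wise recovery scoring (note that a coupling difference in the
#' network spheres is also a true neighbourhood-synchrony difference, so
#' the concordance contrast may legitimately report clusters there too).
#'
#' @param spec a [cohort_spec].
#' @return A list with linear voxel index vectors `fc_effect_voxels` and
#'   `reho_effect_voxels`, plus `fc_components` and `reho_components`
#'   (lists of per-sphere index vectors).
#' @export
ground_truth_voxels <- function(spec) {
  brain <- cohort_mask(spec)
  fc_comp <- lapply(spec$dmn_rois, roi_voxel_indices,
                    grid = spec$grid, brain = brain)
  reho_comp <- lapply(spec$reho_effect_rois, roi_voxel_indices,
                      grid = spec$grid, brain = brain)
  list(fc_effect_voxels = sort(unique(unlist(fc_comp))),
       reho_effect_voxels = sort(unique(unlist(reho_comp))),
       fc_components = fc_comp, reho_components = reho_comp)
}

#' Generate a cohort on disk
#'
#' Writes one 4D NIfTI volume and one rp-style motion trace per subject, a
#' manifest TSV (subject id, group, age, sex, education), the brain mask,
#' and a ground-truth JSON (effect voxel indices, motion-outlier ids,
#' group labels) under one directory. Fully deterministic given
#' `spec$rng_seed`.
#'
#' @param spec a [cohort_spec].
#' @param dir output directory; must not already contain a manifest unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into a previously used directory.
#' @return Invisibly, a list with the manifest data.frame, ground truth,
#'   and file paths.
#' @export
generate_cohort <- function(spec, dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  manifest_path <- file.path(dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite)
    stop("cohort directory already populated; pass overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n <- spec$n_patients + spec$n_controls
  ids <- c(sprintf("pat%02d", seq_len(spec$n_patients)),
           sprintf("con%02d", seq_len(spec$n_controls)))
  groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))

  set.seed(spec$rng_seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  outlier <- logical(n)
  if (spec$n_motion_outliers[1] > 0)
    outlier[sample(which(groups == "patient"), spec$n_motion_outliers[1])] <- TRUE
  if (spec$n_motion_outliers[2] > 0)
    outlier[sample(which(groups == "control"), spec$n_motion_outliers[2])] <- TRUE
  gi <- as.integer(groups == "control") + 1L   # 1 = patient, 2 = control
  age <- round(pmin(pmax(stats::rnorm(n, spec$age_mean[gi], spec$age_sd[gi]),
                         14), 50), 1)
  sex <- ifelse(stats::runif(n) < 0.52, "male", "female")
  education <- sample(c("low", "secondary", "higher"), n, replace = TRUE,
                      prob = c(0.10, 0.46, 0.44))

  bold_paths <- file.path(dir, paste0(ids, "_bold.nii"))
  rp_paths <- file.path(dir, paste0(ids, "_rp.txt"))
  for (i in seq_len(n)) {
    subj <- generate_subject(spec, groups[i], subj_seeds[i], outlier[i])
    write_stat_nifti(subj$volume, bold_paths[i])
    write_motion_trace(subj$motion, rp_paths[i])
  }
  brain <- cohort_mask(spec)
  RNifti::writeNifti(as_nifti_image(array(as.numeric(brain$inside),
                                          dim = spec$grid$dims), spec$grid),
                     file.path(dir, "mask.nii"), datatype = "uint8")

  manifest <- data.frame(subject = ids, group = groups, age = age, sex = sex,
                         education = education,
                         bold = basename(bold_paths), motion = basename(rp_paths),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth <- c(ground_truth_voxels(spec),
             list(motion_outlier_ids = ids[outlier],
                  groups = stats::setNames(groups, ids),
                  grid_dims = spec$grid$dims))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(list(manifest = manifest, ground_truth = truth, dir = dir,
                 bold = bold_paths, motion = rp_paths))
}
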