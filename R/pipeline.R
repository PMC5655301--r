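#' Run configuration
#'
#' Collects everything one end-to-end study run needs. Either `cohort_dir`
#' points at an existing cohort (manifest.tsv + per-subject NIfTI and
#' motion files, as written by [generate_cohort()]), or `simulate` holds a
#' [cohort_spec] to generate one under the output directory first.
#'
#' @param output_dir directory for all run outputs.
#' @param cohort_dir existing cohort directory, or `NULL` to simulate.
#' @param simulate a [cohort_spec] used when `cohort_dir` is `NULL`.
#' @param preprocess a [preprocess_config].
#' @param seed a [seed_spec].
#' @param neighborhood homogeneity neighbourhood size (7, 19 or 27).
#' @param p_threshold voxelwise two-tailed p threshold.
#' @param extent minimum cluster size, exclusive.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param tr_seconds TR override applied when reading volumes (`NULL`:
#'   trust headers).
#' @param rng_seed seed for any simulation randomness (overrides the one in
#'   `simulate` when given).
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, cohort_dir = NULL, simulate = cohort_spec(),
                       preprocess = preprocess_config(), seed = seed_spec(),
                       neighborhood = 27L, p_threshold = 0.001, extent = 50L,
                       connectivity = 26L, tr_seconds = NULL,
                       rng_seed = NULL) {
  stopifnot(neighborhood %in% c(7L, 19L, 27L), p_threshold > 0,
            p_threshold < 1, extent >= 0, connectivity %in% c(6L, 18L, 26L))
  if (!is.null(rng_seed) && !is.null(simulate))
    simulate$rng_seed <- as.integer(rng_seed)
  structure(list(output_dir = output_dir, cohort_dir = cohort_dir,
                 simulate = simulate, preprocess = preprocess, seed = seed,
                 neighborhood = as.integer(neighborhood),
                 p_threshold = p_threshold, extent = as.integer(extent),
                 connectivity = as.integer(connectivity),
                 tr_seconds = tr_seconds),
            class = "run_config")
}

config_keys <- list(
  cohort = c("dir", "n_patients", "n_controls", "n_timepoints", "tr_seconds",
             "fc_coupling_controls", "fc_coupling_patients",
             "reho_local_weight_controls", "reho_local_weight_patients",
             "noise_sd", "drift_slope_sd", "n_motion_outliers", "rng_seed"),
  preprocess = c("n_discard", "max_translation_mm", "max_rotation_deg",
                 "fwhm_mm", "band_low_hz", "band_high_hz", "stage_order"),
  seed = c("center_mm", "radius_mm"),
  reho = "neighborhood",
  group = c("p_threshold", "extent", "connectivity"),
  output_dir = NULL, rng_seed = NULL)

#' Read and validate a YAML run configuration
#'
#' Missing keys are filled with the package defaults (discard 5 volumes,
#' 8 mm FWHM, 0.01-0.08 Hz band, seed (-12, -47, 32) r = 10 mm,
#' 27-voxel neighbourhood, p < 0.001, extent > 50 voxels); unknown keys are
#' rejected by name so typos cannot silently change a run.
#'
#' @param path YAML file; may be empty (all defaults). Recognised sections:
#'   `cohort`, `preprocess`, `seed`, `reho`, `group`, plus top-level
#'   `output_dir` and `rng_seed`.
#' @param output_dir fallback output directory when the file names none.
#' @return A normalized [run_config].
#' @export
validate_config <- function(path, output_dir = NULL) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), names(config_keys))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(config_keys), collapse = ", "))
  for (sec in intersect(names(raw), c("cohort", "preprocess", "seed",
                                      "reho", "group"))) {
    bad <- setdiff(names(raw[[sec]]), config_keys[[sec]])
    if (length(bad))
      stop(sprintf("unknown config key(s) under '%s': %s; valid: %s", sec,
                   paste(bad, collapse = ", "),
                   paste(config_keys[[sec]], collapse = ", ")))
  }
  co <- raw$cohort %||% list()
  pp <- raw$preprocess %||% list()
  sd <- raw$seed %||% list()

  band <- c(pp$band_low_hz %||% 0.01, pp$band_high_hz %||% 0.08)
  if (band[1] >= band[2])
    stop("validation error at preprocess.band: low must be below high")
  pre <- preprocess_config(
    n_discard = pp$n_discard %||% 5L,
    max_translation_mm = pp$max_translation_mm %||% 10,
    max_rotation_deg = pp$max_rotation_deg %||% 1,
    fwhm_mm = pp$fwhm_mm %||% 8, band_hz = band,
    stage_order = pp$stage_order %||% "presmooth")

  sim <- NULL
  if (is.null(co$dir)) {
    sim <- cohort_spec(
      n_patients = co$n_patients %||% 20L,
      n_controls = co$n_controls %||% 20L,
      n_timepoints_acquired = co$n_timepoints %||% 140L,
      tr_seconds = co$tr_seconds %||% 3.0,
      fc_coupling_controls = co$fc_coupling_controls %||% 0.8,
      fc_coupling_patients = co$fc_coupling_patients %||% 0.35,
      reho_local_weight_controls = co$reho_local_weight_controls %||% 0.90,
      reho_local_weight_patients = co$reho_local_weight_patients %||% 0.45,
      noise_sd = co$noise_sd %||% 1.0,
      drift_slope_sd = co$drift_slope_sd %||% 0.01,
      n_motion_outliers = co$n_motion_outliers %||% c(0L, 0L),
      rng_seed = co$rng_seed %||% raw$rng_seed %||% 20170828L)
  }
  run_config(
    output_dir = raw$output_dir %||% output_dir %||%
      stop("no output_dir in config and none supplied"),
    cohort_dir = co$dir, simulate = sim, preprocess = pre,
    seed = seed_spec(center_mm = sd$center_mm %||% c(-12, -47, 32),
                     radius_mm = sd$radius_mm %||% 10),
    neighborhood = (raw$reho %||% list())$neighborhood %||% 27L,
    p_threshold = (raw$group %||% list())$p_threshold %||% 0.001,
    extent = (raw$group %||% list())$extent %||% 50L,
    connectivity = (raw$group %||% list())$connectivity %||% 26L,
    rng_seed = raw$rng_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_cohort_mask <- function(dir, grid) {
  img <- RNifti::readNifti(file.path(dir, "mask.nii"))
  brain_mask(grid, array(as.numeric(img) > 0.5, dim = grid$dims))
}

#' Run the full study pipeline
#'
#' Simulate (or load) a two-group cohort, preprocess every subject with
#' head-motion quality control, compute per-subject regional-homogeneity
#' and seed-connectivity maps, and perform group inference: one-sample
#' t-maps of connectivity per group and two-sample (patient - control)
#' t-maps of both measures with cluster-extent thresholding. Subjects
#' failing QC are excluded from all downstream stages and listed with their
#' motion maxima. Deterministic given the cohort and configuration.
#'
#' @param config a [run_config] (or path to a YAML file for
#'   [validate_config()]).
#' @return An object of class `fmri_study`: QC table, demographics table,
#'   cluster tables for connectivity and homogeneity contrasts, group t
#'   maps, ground-truth overlap (when the cohort carries ground truth), and
#'   a manifest of every file written.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  note <- function(p) files[[length(files) + 1L]] <<- p

  ## cohort
  if (is.null(config$cohort_dir)) {
    cohort_dir <- file.path(out, "cohort")
    generate_cohort(config$simulate, cohort_dir, overwrite = TRUE)
  } else cohort_dir <- config$cohort_dir
  manifest <- utils::read.delim(file.path(cohort_dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  first <- read_bold_nifti(file.path(cohort_dir, manifest$bold[1]),
                           config$tr_seconds)
  grid <- first$grid
  mask <- if (file.exists(file.path(cohort_dir, "mask.nii")))
    read_cohort_mask(cohort_dir, grid) else ellipsoid_mask(grid, margin = 1)

  ## per-subject preprocessing + maps
  cfg <- config$preprocess
  qc <- data.frame(subject = manifest$subject, group = manifest$group,
                   max_translation_mm = NA_real_, max_rotation_deg = NA_real_,
                   pass = NA, stringsAsFactors = FALSE)
  w_maps <- list(); z_maps <- list()
  map_dir <- file.path(out, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject[i]
    trace <- read_motion_trace(file.path(cohort_dir, manifest$motion[i]))
    verdict <- qc_motion(trace, cfg)
    qc$max_translation_mm[i] <- verdict$max_translation_mm
    qc$max_rotation_deg[i] <- verdict$max_rotation_deg
    qc$pass[i] <- verdict$pass
    if (!verdict$pass) next
    vol <- if (i == 1L) first else
      read_bold_nifti(file.path(cohort_dir, manifest$bold[i]),
                      config$tr_seconds)
    pp <- preprocess_subject(vol, mask, cfg)
    w <- if (cfg$stage_order == "presmooth")
      reho_map(pp$smoothed, mask, config$neighborhood)
    else
      gaussian_smooth(reho_map(pp$unsmoothed, mask, config$neighborhood),
                      cfg$fwhm_mm, mask)
    fc <- seed_fc_maps(pp$smoothed, mask, config$seed)
    w_maps[[id]] <- w
    z_maps[[id]] <- fc$z
    note(write_stat_nifti(w, file.path(map_dir, paste0(id, "_reho_w.nii"))))
    note(write_stat_nifti(fc$z, file.path(map_dir, paste0(id, "_fc_z.nii"))))
  }
  utils::write.table(qc, file.path(out, "qc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  note(file.path(out, "qc.tsv"))

  kept <- manifest$subject[qc$pass]
  pat <- intersect(kept, manifest$subject[manifest$group == "patient"])
  con <- intersect(kept, manifest$subject[manifest$group == "control"])
  if (length(pat) < 2L || length(con) < 2L)
    stop(sprintf("group stage refused: %d patients / %d controls passed QC (need >= 2 each)",
                 length(pat), length(con)))

  ## group statistics
  contrasts <- list(
    fc = list(maps = z_maps, label = "functional connectivity (z)"),
    reho = list(maps = w_maps, label = "regional homogeneity (W)"))
  cluster_tables <- list(); t_maps <- list(); one_sample <- list()
  for (nm in names(contrasts)) {
    mp <- contrasts[[nm]]$maps
    tmap <- two_sample_t(mp[pat], mp[con])
    t_maps[[nm]] <- tmap
    note(write_stat_nifti(tmap, file.path(out, paste0(nm, "_t.nii"))))
    recs <- threshold_clusters(tmap, p_thresh = config$p_threshold,
                               extent = config$extent,
                               connectivity = config$connectivity)
    cluster_tables[[nm]] <- list(
      records = recs,
      table = cluster_report(recs,
                             contrast = paste("patient - control,",
                                              contrasts[[nm]]$label),
                             path = file.path(out, paste0(nm, "_clusters.tsv"))))
    note(file.path(out, paste0(nm, "_clusters.tsv")))
  }
  one_sample$fc_patient <- one_sample_t(z_maps[pat])
  one_sample$fc_control <- one_sample_t(z_maps[con])

  demo <- cohort_table(manifest[manifest$subject %in% kept, , drop = FALSE],
                       path = file.path(out, "demographics.tsv"))
  note(file.path(out, "demographics.tsv"))

  ## ground-truth recovery, when available
  overlap <- NULL
  truth_path <- file.path(cohort_dir, "ground_truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE)
    dec <- function(recs) recs[recs$sign == "decrease", , drop = FALSE]
    inc <- function(recs) sum(recs$sign == "increase")
    overlap <- list(
      fc_dice = recovery_dice(dec(cluster_tables$fc$records),
                              truth$fc_components),
      reho_dice = recovery_dice(dec(cluster_tables$reho$records),
                                truth$reho_components),
      n_increased_fc = inc(cluster_tables$fc$records),
      n_increased_reho = inc(cluster_tables$reho$records))
  }

  structure(list(config = config, cohort_dir = cohort_dir, qc = qc,
                 n_patients = length(pat), n_controls = length(con),
                 demographics = demo, cluster_tables = cluster_tables,
                 t_maps = t_maps, one_sample = one_sample,
                 overlap = overlap, files = files),
            class = "fmri_study")
}

#' @export
print.fmri_study <- function(x, ...) {
  cat("Resting-state fMRI group study\n")
  cat(sprintf("  subjects passing motion QC: %d patients, %d controls (%d excluded)\n",
              x$n_patients, x$n_controls, sum(!x$qc$pass)))
  for (nm in names(x$cluster_tables)) {
    recs <- x$cluster_tables[[nm]]$records
    cat(sprintf("  %s contrast: %d decreased, %d increased cluster(s)\n",
                nm, sum(recs$sign == "decrease"), sum(recs$sign == "increase")))
  }
  if (!is.null(x$overlap))
    cat(sprintf("  ground-truth Dice: FC %.3f, ReHo %.3f\n",
                x$overlap$fc_dice, x$overlap$reho_dice))
  invisible(x)
}

#' @export
summary.fmri_study <- function(object, ...) {
  print(object)
  cat("\nExcluded subjects:\n")
  print(object$qc[!object$qc$pass, c("subject", "group",
                                     "max_translation_mm",
                                     "max_rotation_deg")], row.names = FALSE)
  for (nm in names(object$cluster_tables)) {
    cat(sprintf("\n%s peak table:\n", nm))
    print(object$cluster_tables[[nm]]$table, row.names = FALSE)
  }
  cat("\nDemographics:\n")
  print(object$demographics, row.names = FALSE)
  invisible(object)
}
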