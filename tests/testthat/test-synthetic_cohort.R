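test_that("subject generation is deterministic and shaped by the spec", {
  spec <- small_spec()
  a <- generate_subject(spec, "control", subject_seed = 5L)
  b <- generate_subject(spec, "control", subject_seed = 5L)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$motion$translations_mm, b$motion$translations_mm)
  expect_equal(a$volume$n_timepoints, 60L)
  expect_equal(a$volume$tr_seconds, 3.0)
  c2 <- generate_subject(spec, "control", subject_seed = 6L)
  expect_false(identical(a$volume$values, c2$volume$values))

  # out-of-mask voxels are empty; in-mask carry baseline-level signal
  mask <- cohort_mask(spec)
  expect_true(all(a$volume$values[rep(!mask$inside, 60L)] == 0))
  expect_gt(mean(a$volume$values[rep(mask$inside, 60L)]), 50)
})

test_that("zero coupling leaves seed correlation at chance level", {
  spec <- small_spec(fc_coupling_controls = 0, fc_coupling_patients = 0,
                     subject_effect_sd = 0, background_coupling_sd = 0)
  mask <- cohort_mask(spec)
  truth <- ground_truth_voxels(spec)
  rs <- c()
  for (s in 1:8) {
    subj <- generate_subject(spec, "control", subject_seed = 100L + s)
    vol <- detrend_linear(discard_initial(subj$volume, 5L), mask)
    sm <- seed_mask(vol$grid, small_seed_spec(), mask)
    ts <- seed_timeseries(vol, sm)
    r <- pearson_map(vol, ts, mask)
    # correlations at the non-seed DMN target sphere
    target <- setdiff(truth$fc_effect_voxels, which(sm$inside))
    rs <- c(rs, r$values[target])
  }
  expect_gt(length(rs), 200)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("stronger coupling yields stronger in-ROI seed correlation", {
  mean_target_r <- function(coupling, seed_off) {
    spec <- small_spec(fc_coupling_controls = coupling,
                       fc_coupling_patients = coupling,
                       subject_effect_sd = 0, background_coupling_sd = 0)
    mask <- cohort_mask(spec)
    truth <- ground_truth_voxels(spec)
    out <- numeric(0)
    for (s in 1:10) {
      subj <- generate_subject(spec, "control", subject_seed = seed_off + s)
      vol <- detrend_linear(discard_initial(subj$volume, 5L), mask)
      sm <- seed_mask(vol$grid, small_seed_spec(), mask)
      r <- pearson_map(vol, seed_timeseries(vol, sm), mask)
      out <- c(out, mean(r$values[setdiff(truth$fc_effect_voxels,
                                          which(sm$inside))]))
    }
    mean(out)
  }
  # same subject seeds, hence the same noise structure, at two couplings
  expect_gt(mean_target_r(0.8, 500L), mean_target_r(0.3, 500L))
})

test_that("cohort generation writes a complete, deterministic bundle", {
  spec <- small_spec(n_patients = 3L, n_controls = 3L,
                     n_motion_outliers = c(1L, 0L), rng_seed = 77L)
  d1 <- file.path(tempdir(), "cohA")
  out <- generate_cohort(spec, d1, overwrite = TRUE)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  expect_true(file.exists(file.path(d1, "ground_truth.json")))
  expect_equal(nrow(out$manifest), 6L)
  expect_equal(sum(out$manifest$group == "patient"), 3L)
  expect_equal(sum(out$manifest$group == "control"), 3L)
  # group labels partition the cohort
  expect_setequal(out$manifest$subject,
                  c(sprintf("pat%02d", 1:3), sprintf("con%02d", 1:3)))

  # exactly the designated patient trace violates QC
  cfg <- preprocess_config()
  fails <- vapply(out$manifest$motion, function(f)
    !qc_motion(read_motion_trace(file.path(d1, f)), cfg)$pass, logical(1))
  expect_equal(sum(fails), 1L)
  expect_equal(unname(out$manifest$subject[fails]),
               out$ground_truth$motion_outlier_ids)
  expect_match(out$ground_truth$motion_outlier_ids, "^pat")

  # refusal without overwrite; determinism with it
  expect_error(generate_cohort(spec, d1), "overwrite")
  d2 <- file.path(tempdir(), "cohB")
  generate_cohort(spec, d2, overwrite = TRUE)
  v1 <- read_bold_nifti(file.path(d1, "pat01_bold.nii"))
  v2 <- read_bold_nifti(file.path(d2, "pat01_bold.nii"))
  expect_identical(v1$values, v2$values)
  m1 <- utils::read.delim(file.path(d1, "manifest.tsv"))
  m2 <- utils::read.delim(file.path(d2, "manifest.tsv"))
  expect_identical(m1, m2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("spec validation rejects inconsistent cohorts", {
  expect_error(cohort_spec(n_patients = 0L), "n_patients")
  expect_error(cohort_spec(fc_coupling_controls = 0.3,
                           fc_coupling_patients = 0.8), "decreased")
  expect_error(cohort_spec(fc_coupling_controls = 1.4), "\\[0, 1\\]")
  expect_error(cohort_spec(n_motion_outliers = c(25L, 0L)), "within the group")
  # ROI outside the grid is a geometry error at generation time
  bad <- cohort_spec(grid = image_grid(c(14L, 14L, 14L), 3,
                                       origin_mm = c(-21, -21, -21)),
                     n_timepoints_acquired = 60L,
                     dmn_rois = list(list(center_mm = c(900, 0, 0),
                                          radius_mm = 6)))
  expect_error(generate_subject(bad, "control", 1L), "empty")
})

test_that("ground-truth voxel sets lie inside the brain mask", {
  spec <- small_spec()
  truth <- ground_truth_voxels(spec)
  inside <- which(cohort_mask(spec)$inside)
  expect_true(all(truth$fc_effect_voxels %in% inside))
  expect_true(all(truth$reho_effect_voxels %in% inside))
  expect_equal(sort(unique(unlist(truth$fc_components))),
               truth$fc_effect_voxels)
  expect_equal(length(truth$fc_components), length(spec$dmn_rois))
  expect_gt(length(truth$fc_effect_voxels), 50)
})
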