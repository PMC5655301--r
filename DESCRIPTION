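Package: restfmri
Title: Regional Homogeneity and Seed-Based Connectivity for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of resting-state BOLD fMRI cohorts:
    per-subject preprocessing (initial-volume discard, head-motion quality
    control, Gaussian spatial smoothing, linear detrending, ideal band-pass
    filtering), regional homogeneity maps via Kendall's coefficient of
    concordance over voxel neighbourhoods, seed-based default-mode-network
    functional connectivity with Fisher's r-to-z transform, and group-level
    voxelwise t statistics with cluster-extent thresholding and peak tables.
    Includes a synthetic two-group BOLD cohort generator with implanted,
    recoverable connectivity and homogeneity effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
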