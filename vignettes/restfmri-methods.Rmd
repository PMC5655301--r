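---
title: "Methods: regional homogeneity and seed-based connectivity in restfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional homogeneity and seed-based connectivity in restfmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restfmri)
```

# What the package computes

`restfmri` implements a complete group analysis of resting-state BOLD fMRI
cohorts built from two complementary voxelwise measures:

* **Regional homogeneity (ReHo)** — for every brain voxel, Kendall's
  coefficient of concordance $W$ between the voxel's time series and those
  of its neighbours in a cubic neighbourhood (default $K = 27$: the voxel
  and its 26 adjacent voxels). With $R_i$ the across-series rank sum at
  timepoint $i$ and $\bar R = (n+1)K/2$,
  $$W = \frac{\sum_i R_i^2 - n \bar R^2}{\tfrac{1}{12} K^2 (n^3 - n)},
  \qquad W \in [0, 1].$$
  $W = 1$ means the $K$ series are perfectly co-monotone; under
  independence $E[W] = 1/K$, and $K(n-1)W$ is the Friedman chi-square.
* **Seed-based functional connectivity** — the Pearson correlation $r$
  between every voxel's series and the mean series of a spherical seed
  (default: 10 mm radius at the precuneus, $(-12, -47, 32)$ mm, the
  posterior node of the default mode network), mapped through Fisher's
  variance-stabilising transform $z = \tfrac12 \ln\frac{1+r}{1-r}$.

Group inference is the classical neuroimaging pipeline: per-voxel
one-sample $t$ (within-group connectivity) and pooled-variance two-sample
$t$ (patients minus controls, so decreases are negative), a voxelwise
two-tailed threshold $p < 0.001$, connected-component labelling (default
26-connectivity) separately per sign, and a strict cluster-extent rule
(clusters of more than 50 voxels are reported). This is *uncorrected*
cluster-extent inference — the extent heuristic is the only multiplicity
control, matching long-standing practice in clinical resting-state
studies; no random-field or permutation correction is attempted.

A note on the $r$-to-$z$ step: the transform is implemented as
$\operatorname{artanh}(r)$, which downstream normal-theory $t$-tests
require. A raw-ratio variant $(1+r)/(1-r)$ occasionally seen in print is
available as `fisher_z(..., variant = "printed")` for comparison only; it
is not variance-stabilising and must not be fed to $t$-tests.

# Preprocessing chain

Per subject, in the default (`stage_order = "presmooth"`) composition:

1. **Discard** the first `n_discard = 5` volumes (scanner equilibration
   and subject accommodation), e.g. 140 acquired points yield 135 analyzed
   points.
2. **Motion QC** from six-column realignment-parameter traces
   (translations in mm, rotations in radians): a subject is excluded when
   any axis reaches 10 mm translation or 1 degree rotation. The limits are
   evaluated per axis, as phrased in the motion-exclusion conventions this
   chain follows; both are config-exposed (the 10 mm default is
   deliberately permissive — tighten it for stricter cohorts).
3. **Spatial smoothing** with an isotropic Gaussian, FWHM 8 mm
   ($\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, converted to voxel units
   per axis). The kernel is renormalised over the in-mask support
   (masked image smoothed, divided by the smoothed mask), so constants are
   preserved exactly and out-of-mask voxels never leak in.
4. **Linear detrending**: per-voxel least-squares line (intercept + slope)
   removed. The mean goes with it; correlations and rank concordance are
   invariant to that choice.
5. **Ideal band-pass** 0.01–0.08 Hz: discrete Fourier coefficients at
   frequencies $f_k = k/(nT_R)$ strictly outside the band (and the DC
   term) are zeroed. A frequency-domain projection is deterministic and
   idempotent, which the test suite exploits.

Computing homogeneity on smoothed data (the default) inflates baseline
$W$ everywhere, since smoothing correlates neighbours by construction;
group contrasts are unaffected because both groups are smoothed alike.
`stage_order = "conventional"` instead computes $W$ on unsmoothed series
and smooths the $W$ map afterwards, the common alternative; connectivity
always uses smoothed series.

Spatial normalisation is *not* implemented: volumes are assumed already on
a common grid (the synthetic cohort is constructed that way), since
registration is an orthogonal, heavyweight problem handled by dedicated
tools. Slice-timing correction, nuisance regression and scrubbing are
likewise out of scope.

# The synthetic cohort generator

Clinical resting-state cohorts of this design are rarely public, so
validation rests on a generator whose ground truth is known exactly.
Every voxel's series is

$$y_v(t) = \text{baseline} + \beta_v t
  + (c_s + b_s)\, s(t)\,[v \in \text{network ROIs}]
  + b_s\, s(t)\,[v \notin \text{network ROIs}]
  + w_s\, u_{R(v)}(t)\,[v \in \text{synchrony ROIs}]
  + \varepsilon_v(t),$$

where $s$ (one shared network signal per subject) and $u_R$ (one common
signal per synchrony ROI) are unit-variance white noise filtered with the
same ideal 0.01–0.08 Hz mask preprocessing applies — guaranteeing the
implanted structure survives filtering — and $\varepsilon$ is white noise
(sd 1) mixed with its 6-neighbour mean by a per-subject weight
(mean 0.15, sd 0.05), emulating subject-varying intrinsic smoothness.

The effect structure mirrors a decreased-connectivity /
decreased-homogeneity patient phenotype:

* $c_s$, the network coupling, is drawn per subject around a group mean
  (controls 0.80, patients 0.35; sd 0.12, truncated to $[0,1]$);
* $w_s$, the local-synchrony weight, likewise (controls 0.90, patients
  0.45);
* $b_s \sim N(0, 0.10)$ is a brain-wide coupling fluctuation, identical
  in distribution across groups.

The three subject-level variance components deserve emphasis. Without
them, between-subject variance of the $z$ and $W$ maps collapses to pure
estimation noise: group $|t|$ peaks around 40 (an order of magnitude above
anything clinical tables report) and — because out-of-ROI estimation noise
is even smaller — significance spreads far beyond the implanted support.
With them, in-ROI peak $|t|$ at the default 20 vs 20 cohort lands in the
4–9 range typical of published patient/control contrasts, and clusters
localise to the implanted spheres. The effect-size defaults were
calibrated to that reported peak-$t$ magnitude, then frozen.

Geometry defaults: a desk-scale 24 × 28 × 24 grid at 3 mm (origin
$(-36, -89, -4)$ mm, so coordinates span a brain-like envelope and the
default seed centre falls on a voxel centre), an ellipsoidal brain mask
(5688 voxels), two network spheres (the seed sphere and a posterior
parietal target at $(9, -71, 35)$) and one synchrony sphere at
$(6, -27, 42)$, all 10 mm radius (171 voxels each — comfortably above the
50-voxel extent threshold). Motion traces are random walks scaled to stay
inside the QC limits (peak translation 0.3–2 mm), except for designated
outliers scaled to violate them (11–15 mm); demographics echo a typical
epilepsy cohort (patients 27.9 ± 8.3 y, controls 29.1 ± 7.5 y).

What the generator does **not** emulate: anatomy, scanner physics, slice
timing, susceptibility and motion artifacts in the images themselves,
physiological noise spectra, or spatially varying autocorrelation. Passing
recovery tests therefore demonstrates that the pipeline's statistics
recover known effects under its own assumptions — not that it is robust to
everything real data does.

# Validation experiments

The test suite and `scripts/acceptance.R` run three simulation
experiments end-to-end:

* **Null concordance calibration.** On an independent white-noise volume
  ($n = 135$, $K = 27$), mean $W$ over 512 interior voxels spaced three
  apart (disjoint neighbourhoods, hence independent) must sit within
  3 standard errors of $1/27$.
* **Type-I calibration.** Ten replicate null cohorts (8 vs 8, identical
  group parameters, no implanted signal) are pushed through
  preprocess → connectivity → two-sample $t$; the voxelwise rejection
  rate at $p < 0.001$ must lie within three binomial standard errors of
  0.001. These cohorts are generated without smoothing and without the
  shared background components: smoothing does not change the per-voxel
  null distribution of the pooled $t$, but it correlates voxels, which
  would invalidate the binomial error bar; the experiment is designed so
  its error model is exact.
* **Effect recovery.** On the default 20 vs 20 cohort, the
  patient-minus-control contrasts must report decrease-direction clusters
  only, and each implanted effect sphere must be recovered: the score is
  the mean over implanted spheres of the best-matching reported cluster's
  Dice overlap, required to reach 0.5. Component-wise best-pair Dice is
  used rather than a union Dice because the concordance contrast may
  legitimately also detect the network spheres (a coupling difference *is*
  a neighbourhood-synchrony difference there); a union score would punish
  those true detections, while a missed sphere still scores 0 and drags
  the mean down.

Problem sizes (desk-scale grid, 20 + 20 subjects, 10 null replicates at
14³) were chosen so the full suite runs in minutes on one core; the same
code paths accept full MNI-size grids.

# Numerical and design choices

* Ranks use average-tie handling without a tie-correction term in the
  denominator of $W$: BOLD series are continuous, so exact ties are
  measure-zero. Documented limitation for heavily quantised input.
* Neighbourhoods truncate at the mask boundary (effective $K$ = in-mask
  count, flagged per voxel; $K < 2$ yields $W = 0$), keeping the map
  support equal to the mask rather than eroding cluster geometry.
* No division of $W$ maps by their global mean by default (raw $W$ is
  compared); `stat_map` metadata records parameters for provenance.
* Seed voxels are selected by centre-to-centre distance with a $\le$
  comparison, no partial-volume weighting, and remain in the analysed
  mask (their $r \approx 1$ is shared by both groups, so contrasts are
  unaffected).
* $|r| \ge 1 - 10^{-7}$ is clamped to $\pm\operatorname{artanh}(1-10^{-7})$
  and flagged; $t$-to-$z$ conversion matches one-tailed probabilities on
  the log scale, so large $|t|$ does not overflow.
* Equal-variance pooled $t$ (df $n_a + n_b - 2$), not Welch, matching the
  classical group model; zero-variance voxels are flagged, not errors.
* The extent rule is strict (`> 50` means 51 is the smallest reported
  cluster); cluster connectivity defaults to 26 and is configurable
  (6/18/26) since labelling conventions differ between toolkits.
* Pipeline runs are deterministic given the configuration and master
  seed; per-subject seeds are drawn once from the master stream. Stage
  outputs are simply rewritten on re-run — content-hash caching was
  considered and rejected as disproportionate state for minutes-scale
  runs.
* Peak tables print an equivalent normal $Z$ per cluster peak via exact
  probability matching of Student tails. Published tables produced by
  other toolkits may use different $t\!\to\!Z$ conventions, so printed
  $Z$ values are not comparable across software at high precision.

# Known limitations

Uncorrected cluster-extent inference does not control familywise error;
the generator's realism gaps are listed above; covariate adjustment
(age/sex) is not implemented — cohorts are assumed matched, and the
demographics module exists precisely to check that; anatomical labelling
of cluster peaks is a free-text column left blank (no atlas lookup).
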