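---
title: "Quantifying lacZ reporter activity in micro-CT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lacZ reporter activity in micro-CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xgalvox)
```

## The measurement model

A reconstructed micro-CT volume of an X-gal-stained, dehydrated,
paraffin-embedded brain assigns each voxel a grayscale value proportional to
local X-ray attenuation. That value is modeled as the sum of two
contributions: the endogenous radiodensity of the dehydrated tissue, and the
density added by the brominated indigo precipitate that the β-galactosidase
reaction deposits wherever the *lacZ* reporter is active. Bromine's mass
attenuation coefficient at ~40 kV (6.832) is about 25-fold that of brain
gray matter (0.270), which is why the deposit is visible at all;
`attenuation_fold_ratio()` records this physics sanity check.

Because the added density is proportional to the amount of deposited
product, and hence to reporter activity, differences in gray value between
regions — or between a reporter-carrying brain and a wild-type littermate —
carry relative information about expression level. Absolute enzyme-activity
units would require a dedicated β-gal calibration phantom and are out of
scope.

All grayscale arithmetic operates on native reconstruction values; integer
TIFF inputs are widened to double but never rescaled to [0, 1], because every
threshold below is defined on the native scale.

## Hounsfield calibration

`fit_calibration()` implements the standard two-point affine calibration:
the arithmetic means of user-labeled water and air reference regions are
mapped to 0 HU and −1000 HU. Two anchor equations determine the map
uniquely:

\[
s = \frac{1000}{\bar x_{water} - \bar x_{air}},\qquad
b = -s\,\bar x_{water}.
\]

The fit refuses a non-positive gap (water mean must exceed air mean) and the
anchor identities are exact to well below 1e−9 HU on every fitted model.
Because the map is affine, ROI means may be calibrated before or after
averaging with identical results — a property the test suite exercises
directly. The references may be labeled inside the sample scan or come from
a separate phantom scan; in the latter case identical acquisition settings
are the caller's responsibility (the model records a free-text
`acquisition_id` for audit, since no enforcement is possible from image data
alone). Calibration is optional for within-volume relative analysis: the
subtraction- and SD-threshold-based comparisons are invariant under any
affine intensity map applied consistently, so the pipeline permits raw gray
values throughout and tags every report with the units used.

## Paraffin exclusion by Otsu thresholding

`exclude_background()` builds an equal-width histogram (default 256 bins,
the 8-bit display convention of desktop CT software; the bin count is a
configuration knob) over the ROI's min–max range and selects the interior
bin edge maximizing the between-class variance
\(\omega_0\omega_1(\mu_0-\mu_1)^2\), with bin centers as class values.
Voxels **at or above** the threshold count as tissue; ties between candidate
edges resolve to the highest tied edge, i.e. the lower edge of the first
occupied upper-class bin. Together the two conventions are deterministic and
conservative: equality never excludes potential reporter signal, and in a
histogram with an empty gap between classes the threshold sits against the
upper class rather than floating in the gap. The implementation is checked
against an independent exhaustive search over all edges on 1000 random
histograms.

The histogram may be built per-ROI or globally (pass no ROI): which of the
two a published whole-dataset exclusion corresponds to is not always
recorded, so both are exposed. Note that Otsu exclusion is only meaningful
when the ROI actually contains background: applied to a mask that already
delineates pure tissue it will split the tissue distribution itself. The
pipeline therefore exposes `otsu$enabled`, and the synthetic end-to-end
tests disable it because generator masks are exact.

## ROI statistics, background correction, and SD grading

`roi_stats()` reports the **population** SD (divide by *n*): the ROI is the
entire population of voxels considered, not a sample from a larger one. The
difference from the sample SD is negligible at realistic ROI sizes but is
fixed for exactness. Voxels are accumulated in ascending flat-index order
with long-double accumulation, so results are reproducible run to run.

Two threshold regimes coexist because both occur in practice:

* **WT regime** — the background-correction threshold is the wild-type
  region's mean + 1 SD, subtracted from the matched reporter region
  (per-region mean via `corrected_region_means()`, or per-voxel via
  `corrected_voxel_image()`; whether a published figure used one or the
  other is often ambiguous, so both are provided). Negative differences
  clamp to 0 — only positive brightness differences are reported — with the
  signed value available behind `clamp = FALSE` for diagnostics.
* **SELF regime** — grade thresholds mean + 1/2/3 SD are derived from the
  reporter dataset itself and the identical thresholds object is then
  re-applied to the wild-type volume for a like-for-like comparison.

Grading uses half-open bins `[t1, t2)`, `[t2, t3)` with the top bin closed
at the maximum, and the conservation invariant (grade counts partition the
graded voxels exactly) is asserted on every constructed grade map. With a
degenerate SD of 0 all three thresholds coincide at the mean; values at or
above it then grade "high", and a warning flags the situation. Per-ROI maps
over disjoint ROIs merge by voxelwise union (`merge_roi_grades()`), keeping
per-ROI threshold provenance; any overlap is an error rather than a silent
precedence rule.

An important consequence of the mean + 1 SD rule: for a deposit of added
density Δ occupying fraction *f* of an ROI with noise SD σ, the expected
corrected region value is the mixture excess minus one SD, Δ·f − σ, **not**
Δ·f. The unclamped output recovers exactly this estimand (the parameter
recovery tests verify it at Δ = 1σ, 2σ, 3σ); the clamped, reported value is
its positive part. Interpreting corrected values therefore requires either
f·Δ > σ or reliance on the grading route.

## Line-profile densitometry

`extract_profile()` samples 1-voxel-wide stretches at voxel-size steps with
nearest-voxel lookup, restricted to grid axes and 45° in-plane diagonals —
no interpolation, since 1-voxel-wide stretches imply on-grid sampling. A
300 μm stretch at 5 μm/voxel yields 61 samples. The default protocol is
three parallel stretches separated by 2 voxels, a paraffin background mean
taken from an equally long stretch through paraffin only (a QC warning fires
if ground-truth labels show the reference crossing tissue), valuewise
subtraction without clamping, then binning.

The phrase "mean and standard error over three related adjacent pixels in
each line" admits two readings, so both are implemented:

* `mode = "triplet"` (default): each line is reduced to means of
  non-overlapping triplets of consecutive samples (61 samples → 20 bins,
  remainder dropped; bin center = mean distance of contributing samples);
  at each bin the three per-line triplet means give mean and SEM
  (sample SD/√3).
* `mode = "across"`: the three lines are combined pixel-by-pixel at each
  position (SEM over n = 3 pixels), with no binning along the line.

`profile_peak()` takes the argmax of bin means, ties to the smallest
distance. The distance axis starts at the profile's start sample — in the
layer phantom, on the molecular side, increasing toward the granular layer.

## The synthetic phantom generator

No real scans ship with the package, so validation runs entirely on
`generate_phantom()` / `generate_pair()` / `generate_layer_phantom()`. Regions are characterized solely by a mean and
SD, so independent homoscedastic Gaussian noise per region is the minimal
faithful model (a Student-t option with df 6 exists for robustness checks).
Defaults, chosen once as plausible for an 8-bit-like reconstruction scale:
paraffin N(20, 2²), cerebrum N(80, 8²), hindbrain N(95, 8²), water
N(200, 2²), air N(10, 1²); whole-brain phantoms use 20 μm voxels and the
layer phantom 5 μm, the two resolutions of the scans being emulated; the
default deposit adds 24 gray units (3 tissue SDs) with activity→density
proportionality κ = 1. The layer phantom uses molecular N(60, 5²) vs
granular N(90, 5²) — the granular layer is the denser — with a Gaussian
deposit band (width 4 voxels, delta 60) centered on the boundary, so the
true profile maximum sits at the boundary.

`generate_pair()` derives two sub-seeds deterministically from the spec
seed, giving matched geometry with independent noise and no deposits in the
wild type — the littermate design. Every phantom carries a truth table
(region memberships, true means/SDs, deposit deltas) that tests verify
against the emitted volume by brute force.

What the phantoms deliberately do **not** emulate: X-ray physics
(source spectrum, Beer–Lambert projection), reconstruction artifacts
(beam hardening, rings, misalignment — assumed corrected upstream), partial
volume effects, spatially correlated noise, and anatomical shape. Passing
tests therefore demonstrate that the statistical machinery is correct under
its stated model, not that the model captures every property of real
reconstructions.

## Validation problem sizes and statistical conventions

The test suite runs the Gaussian grading-limit check on 10⁶ voxels
(fractions vs normal tail masses 84.13/13.59/2.14/0.13% within 3 binomial
SEs), parameter recovery on the default ~24k-voxel cerebrum at three deposit
strengths (3 SEs of the ROI-mean estimator), and peak recovery over 100
seeded layer-phantom pairs (≥95 peaks within ±1 bin of the band center).
Granular-side agreement between reporter and wild-type profiles is assessed
on bins lying beyond the band center + 3 band widths — inside that zone the
band's Gaussian tail differs by construction — and on profiles averaged
across the replicate pairs, mirroring how such profiles are reported as
across-animal averages; agreement means |mean difference| ≤ 3 SEM per bin.

## Numerical and interface choices

* Axis order is fixed `(slice, row, column)`, 1-based in R; slices assemble
  in lexicographic filename order for slice directories and page order for
  multi-page files. Only isotropic voxels are supported; anisotropic input
  is an explicit error.
* Metadata lives in a JSON sidecar (`{"voxel_size_um": ..., "units": ...}`)
  rather than TIFF tags; units default to raw gray.
* The package includes a minimal uncompressed grayscale TIFF codec because
  exact round trips of 32-bit float samples (and unscaled integer writes)
  are required by the IO contract; compressed or otherwise exotic files fall
  back to `tiff::readTIFF`, and multichannel (RGB) pages are rejected as
  volumes. `f32` round trips are bit-exact for values representable in
  single precision; `u8`/`u16` round half to even and refuse out-of-range
  values.
* Operations defined on HU refuse raw-gray volumes and vice versa;
  volume/mask pairs are shape-checked before any computation; every source
  of randomness flows from a single spec/config seed.
* Reports are deterministic: rerunning an identical configuration reproduces
  every CSV/JSON/TIFF output byte for byte, and the manifest stores the
  config with its MD5 hash (no timestamps).

## Known limitations

* Relative quantification only, within a single calibrated dataset; no
  cross-dataset comparison and no absolute enzyme activity.
* ROI masks are user-supplied (or generator truth); no atlas registration or
  automatic anatomical segmentation.
* The mean + 1 SD subtraction estimates Δ·f − σ, so weak or sparse deposits
  (f·Δ ≤ σ) clamp to zero in the reported value — by design, but worth
  remembering when interpreting zeros.
* Line profiles are on-grid only; arbitrary-angle profiles would need
  interpolation, which would blur the 1-voxel-wide protocol being modeled.
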