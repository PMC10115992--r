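---
title: "Evaluating PET attenuation-correction methods on digital head phantoms"
author: "aceval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating PET attenuation-correction methods on digital head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aceval)
```

## The evaluation problem

Amino-acid PET in neuro-oncology is read through a small set of
semi-quantitative measures: the tumor-to-brain ratio (TBR) within a
PET-defined biological tumor volume (BTV), the BTV size itself, the
location of the uptake maximum (biopsy target), the change of these
measures between baseline and follow-up, and — for dynamic acquisitions —
the shape of the time-activity curve (TAC). All of them sit downstream of
attenuation correction: a wrong attenuation map (μ-map) biases the
reconstructed activity, and in post-surgical patients μ-map errors are
common (false bone along implants, metal-induced signal voids, air
cavities mistaken for tissue, missing skull flaps, registration errors).

`aceval` implements the evaluation protocol for comparing one or more test
AC methods against a reference on a per-study basis, plus a synthetic data
generator so that the full pipeline can be exercised, tested, and
regression-checked without patient data.

The package assumes all volumes for one study are co-registered and, after
a single explicit resampling step at pipeline entry (nearest-neighbour for
masks and label maps, trilinear for PET and μ-maps), share one axis-aligned
grid. Physical coordinates are `origin + index · spacing` in mm; no
orientation-matrix handling beyond that is attempted. Registration itself,
DICOM ingestion, skull-stripping, and reconstruction are out of scope:
brain masks are inputs, and reconstruction is replaced by a first-order
bias model (below). The interpolation used when mapping a reference CT
onto the anatomical grid is not standardized in practice, so it is left as
the caller's choice between the two resampling variants rather than fixed.

## Delineation

PET images are first normalized to the mean uptake of a background region
of healthy-appearing brain; each AC method's PET image gets its own
background mean from the same region, so normalization errors propagate
exactly as they would clinically. The BTV is the set of brain-masked
voxels with TBR strictly above the threshold (default 1.6), minus any
exclusion masks for physiological uptake (vessels, pineal body), split
into 26-connected components. Both boundaries are strict ("above 1.6",
"above 1 ml") — the inclusion rule admits a study only when the
*reference* BTV exceeds 1 ml, and excluded studies still contribute to
μ-map metrics, mirroring the two-tier cohort structure such evaluations
report. The BTV is the union of all suprathreshold components: manual
workflows remove physiological foci but do not select a single component,
and keeping the union preserves multifocal disease. The TBR peak is the
suprathreshold maximum; exact ties (possible on noiseless synthetic data)
break to the lowest (z, y, x) position for determinism.

The background region itself comes from a manual/in-house tool in clinical
practice, so its exact geometry is not reproducible. The phantom
generator's stand-in is documented and configurable: a crescent-shaped
band of healthy tissue along the brain surface, in the hemisphere
contralateral to the first lesion, inside an axial slab at 55–80 % of the
brain's height (a proxy for "above the insula"), at least 15 mm from any
lesion or focus, trimmed to 10 ml. Its placement matters less than its
consistency: all methods share the same region.

## Agreement metrics

**μ-map class agreement.** Voxels are classified as air (μ < 0.05 cm⁻¹),
tissue (0.05–0.1, closed interval — both printed boundary values read as
tissue), or bone (> 0.1), inside the head mask and optionally a CT
field-of-view mask. Dice coefficients per class are computed globally and
inside a 50-mm sphere around each BTV component's peak ("center of max"
is read as the component's TBR-max location, not its centroid, matching
how the peak is used elsewhere; a centroid variant would be a one-line
change). Two empty masks have Dice 1 by convention.

**Image similarity.** MAE, SSIM, and (for PET) PSNR. SSIM uses a 3D
Gaussian window of σ = 1.5 voxels with the standard constants K₁ = 0.01,
K₂ = 0.03 and the data range set to the reference maximum over the mask;
whether published evaluations used 2D slices or 3D windows is usually
unstated — 3D is the natural choice for volumetric data and is what the
tests' brute-force oracle implements. PSNR of identical images is reported
as `Inf`.

**Contours.** Dice plus the Hausdorff distance as the maximum of the two
directed maximum surface-voxel distances in mm (surface = mask voxels with
a 6-neighbour outside). A percentile variant (e.g. HD95) is available via
an argument since reports rarely state which was used; the maximum is the
default as the stricter reading.

**Shape deviation.** The clinically relevant contour disagreements are
focal — a new blob, a warp — rather than a one-voxel ribbon along the
whole boundary, which changes volume but not shape. The measure smooths
the binary symmetric difference with a 4-mm-FWHM Gaussian and reports the
volume where the smoothed image reaches its plateau of 1. Numerically the
plateau is approached asymptotically, so "reaches 1" needs a tolerance:
at the default kernel the core of a focal blob of a few kernel widths
(≥ ~6 mm radius) smooths to > 0.99, while a one-voxel displacement shell
peaks near 0.27. The default tolerance 0.02 sits between those regimes
with a wide margin on both sides; it is a parameter (`eps`) for other
kernel/feature scales. Smoothing uses mirror-reflected boundaries so the
statistic is not attenuated at volume edges.

**Peak location.** Euclidean distance between the reference and test
TBR-max positions with a strict < 10 mm criterion, the approximate size of
a stereotactic biopsy sample.

## Clinical metrics and acceptance

TBRmean, TBRmax, SUV statistics, and BTV are taken over the BTV of each
method separately. Differences are judged by paired absolute/relative
criteria with OR-pass semantics — TBRmean ±0.05 or 5 %, TBRmax ±0.1 or
5 %, BTV ±2 ml or 10 % — because a fixed absolute bound is too strict for
large or highly active tumors and a fixed relative bound too strict for
small ones. A study "exceeds criteria" when any metric fails both
branches.

TBR bands for tissue character (reactive TBRmax < 2.0; tumor TBRmax > 2.4
with TBRmean > 2.0; equivocal in between: TBRmax 2.0–2.4 or TBRmean
1.9–2.1) are implemented with the equivocal band carved out first, so the
three classes partition the TBR plane; this matches how borderline cases
are described as moving *out of* the equivocal band under AC changes.

Longitudinal change applies the same criteria to baseline→follow-up
changes: magnitude concordance compares percent changes in percentage
points (or absolute changes against the absolute bound, same OR
semantics — the reading of a jointly-reported bound that is consistent
with the single-time-point rule), and direction concordance compares
signs, with a ±1 % dead band defining "stable" so that sign agreement is
robust to noise.

TAC patterns are classified from the least-squares slope of the
late curve (t ≥ 10 min), normalized by the late mean: beyond ±0.15 %/min
is increasing/decreasing, otherwise plateau. Published readings are
visual; a quantitative proxy is required for a reproducible pipeline, and
the threshold separates the generator's ±20 %-over-30-min patterns
(≈ ±0.6 %/min) from flat curves by a factor of four.

## Agreement statistics

Clinical-metric ratios are analyzed on the log scale (differences of
logs), which is where such strictly positive, right-skewed measures are
closest to normal — normality is checked with Shapiro–Wilk. Results are
exponentiated back to percent differences:

- mean: `100·(exp(d̄) − 1)`
- 95 % CI: `100·(exp(d̄ ± 1.96·SD_d/√n) − 1)`
- 95 % limits of agreement: `100·(exp(d̄ ± 1.96·SD_d) − 1)`

When patients contribute repeated scans, `SD_d` uses the one-way ANOVA
decomposition (between-subject variance from subject means with the
unequal-group-size correction, plus within-subject variance), and the CI
denominator is the number of subjects — the conservative reading of
"corrected for repeated measurements". With one scan per subject both
reduce exactly to the ordinary SD and n. `invert_loa()` recovers the mean
from a reported LoA pair, which doubles as an internal-consistency check
of any published table using these formulas. Paired t-tests are two-sided
at α = 0.05 with no multiplicity adjustment (single-comparison reporting
is mirrored deliberately); identical inputs yield an `NA` p-value sentinel
with a warning rather than a spurious number.

## The phantom generator

The generator emulates the *structure* of the clinical data, not its
radiology:

- nested ellipsoids for scalp (tissue), skull (bone, 6 mm), and brain,
  with μ defaults 0.096/0.151 cm⁻¹ — standard 511 keV soft-tissue/bone
  values placed inside the classification bounds, configurable within
  them;
- activity: background level B (default 2.5 kBq/ml) in brain,
  0.25·B in extracerebral tissue (so skull-strip masking has an observable
  effect), lesions and physiological foci as spheres at `tbr · B`, with an
  optional linear infiltrative margin (`edge_mm`) from full TBR at the
  core radius to background — hard-edged lesions make truth exact
  (the true BTV is the discretized sphere and TBRmean equals the set TBR),
  soft edges make the BTV sensitive to bias, as real tumors are;
- additive Gaussian noise at 5 % of background by default — enough to make
  max-statistics and direction dead-bands non-degenerate, chosen over
  Poisson for simplicity since reconstruction is not modeled;
- artifacts as declarative specs: false-bone patches, metal voids (μ = 0),
  water-filled air cavities, missing skull flaps, rigid shifts;
- a first-order bias model replacing reconstruction: for each voxel,
  `bias = mean over K in-plane directions of exp(∫ Δμ dl)` along full-grid
  lines, the leading-order effect of attenuation-correcting with the wrong
  μ-map. Line integrals are sampled at half the smallest voxel spacing
  with bilinear lookup; since every voxel on a line shares the integral,
  integrals are evaluated per (angle, slice, lateral offset) family and
  interpolated, which is what makes desk-scale cohorts feasible. K = 8
  axial-plane angles by default — the dominant PET geometry; it is an
  approximation, not a reconstruction, and is documented as such;
- dynamic series on the 14-frame 40-min scheme (5×1, 5×3, 4×5 min) with an
  uptake ramp to 10 min and a late pattern of +20 %, 0 %, or −20 % over
  10–40 min.

What it does **not** emulate: scanner PSF, scatter, randoms, Poisson count
statistics, partial-volume effects, realistic cortical anatomy, MR
artifacts themselves (only their μ-map consequences), and reconstruction
nonlinearity. Passing tests therefore demonstrate that the *evaluation
machinery* is correct and that μ-map errors propagate with the right
geometry and magnitude ordering — not that any specific clinical Dice or
agreement value would be reproduced on real patients. Artifact sizes are
user-specified, not calibrated to any cohort.

Cohort generation (`run_phantom_study()`) draws lesion radius 8–14 mm
(TBR 1.9–3.4, 4-mm margins), gives 15 % of subjects sub-inclusion lesions
(radius ≤ 3.2 mm), 25 % an air cavity, 30 % a physiological focus, and
30 % a follow-up scan with the lesion rescaled by 0.8–1.25×. Two built-in
test-method emulations differ only in artifact frequency and severity.
All draws derive from one integer seed; identical seeds give
byte-identical reports.

## Numerical choices

- Gaussian smoothing is separable with mirror-reflected boundaries
  (constants preserved exactly; interior mass preserved to ≈ 10⁻¹⁵).
- σ = FWHM / (2√(2 ln 2)) per axis, converted to voxels by the spacing.
- The bias model returns exactly 1 when the μ-maps are identical, and its
  offset-family evaluation changes by < 0.1 % under step halving on smooth
  fields (a property test).
- Degenerate inputs fail loudly and specifically: empty ROIs/masks,
  non-positive spacing (named axis), negative μ (with count), missing
  frame timing, 2D images, constant vectors in statistics.
- Empty test BTVs make the Hausdorff distance undefined — an error, not a
  sentinel — while empty-vs-empty Dice is 1.

The test suite pins every closed form (voxel volumes, σ conversion, chord
integrals `e^{0.2}`, LoA algebra) and cross-checks Dice, Hausdorff, SSIM,
Gaussian smoothing, and shape deviation against independent brute-force
oracles on small random volumes. Problem sizes are chosen for desk-scale
runs: unit fixtures at 8³–48³, physics and end-to-end checks at 96³
(2 mm voxels, 20-subject identity cohort), and the acceptance script's
cohort at 72³ with 12 subjects; the statistics recovery suites use 100
simulated cohorts. These sizes are the package's own trade-off between
discretization error and turnaround, and all of them are parameters.

## Known limitations

- The bias model is axial-plane-only and first-order; out-of-plane lines
  of response and iterative-reconstruction nonlinearity are not modeled,
  so absolute bias magnitudes are indicative, not calibrated.
- The phantom's geometry is too simple to exercise atlas-registration
  failure modes realistically; `registration_shift` is a whole-map rigid
  translation by whole voxels.
- SUV here is activity concentration: dose/weight normalization cancels
  in every ratio the pipeline reports, but absolute SUV columns are only
  meaningful up to that constant.
- The repeated-measures correction assumes the first follow-up is
  exchangeable with baseline within a subject; time trends are the
  longitudinal module's job, not the variance model's.

```{r example, eval = FALSE}
report <- run_phantom_study(n_subjects = 20, seed = 1)
report$summary$exceeding
report$agreement
```
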