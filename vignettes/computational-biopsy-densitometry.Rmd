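---
title: "Computational-biopsy densitometry for murine lung micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational-biopsy densitometry for murine lung micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Semi-automated, threshold-based segmentation of mouse thorax micro-CT
works well for healthy, aerated lungs but truncates dense pathology:
once lung tissue becomes as radio-dense as heart or liver, an upper
intensity threshold (raw 1850 on the scanner convention used here,
about -206 HU) excludes exactly the voxels that carry the fibrosis
signal. `lungbiopsy` implements the alternative: instead of segmenting
the whole organ, it places two fixed-geometry cylindrical
"computational biopsies" inside the chest cavity — one per lung — on
the slices running through the middle of the lung, and computes
densitometric features from the raw voxel intensities inside them,
excluding airway voxels.

The per-animal pipeline (`run_pipeline()`) is:

1. classify every axial slice into one of five lung-part classes
   (`not_lung`, `only_bronchi`, `top_front`, `middle`, `bottom_rear`);
2. select the contiguous `middle` run (`select_middle_run()`);
3. detect breastbone and spine bounding boxes on those slices
   (`detect_landmarks()`) and reduce them to a rigid chest frame —
   centre, axis angle, scale (`estimate_chest_frame()`);
4. place the two biopsy cylinders from the frame
   (`place_biopsy_rois()`);
5. segment the stack (tissue / airways / bone / background / ignore)
   and remove airway voxels from the biopsy samples;
6. build intensity histograms and compute MLA (mean lung attenuation),
   median, mode, FWHM, skewness, excess kurtosis and the AUC ratio,
   for the left biopsy, right biopsy, both pooled, and the whole
   segmented lung.

## Densitometric features

All analysis uses raw scanner intensities; the linear Hounsfield
conversion (`intensity_to_hu()`) is available for reporting only.
Byte conversion (`to_byte()`) exists solely for the image-analysis
stages, and the densitometry functions refuse byte-converted input by
type.

* **MLA / median** are computed on the raw sample, not from binned
  counts, to avoid binning bias.
* **Mode** is the centre of the maximal-count bin of a uniform
  half-open binning (default width 10 raw units over [0, 4100); the
  aerated peak has SD ~120, so discretization error is negligible).
  Ties break toward lower intensity.
* **FWHM** locates the global histogram peak and interpolates the
  half-height crossings linearly between adjacent bin centres, moving
  outward. On bimodal fibrotic histograms the global-peak rule with
  the low-intensity tie-break is used and flagged (`tie_flag`); a side
  that never falls below half height uses the histogram edge and sets
  `edge_flag`. Histograms with a second dense-tissue peak make
  peak-shape features unreliable — that is precisely why the AUC ratio
  exists.
* **Skewness / kurtosis** use population central moments
  (`m3/m2^1.5`, `m4/m2^2 - 3`; Gaussian gives 0/0).
* **AUC ratio** is the fraction of voxels in the closed aerated range
  [1000, 1500] divided by the fraction in the closed dense range
  [2000, 2500]. Fractions (not raw counts) make it sample-size
  invariant; the orientation is chosen so that it *decreases* with
  fibrosis. A zero dense fraction yields `Inf` with a flag rather than
  an error, since healthy lungs routinely have no mass there.

## Landmarks, chest frame, and biopsy placement

The reference landmark detector thresholds at the bone intensity
(default raw 2900), applies a radius-1 morphological opening, keeps
connected components of at least 20 voxels (scaled with slice area),
and assigns the most anterior centroid to the breastbone and the most
posterior near-midline component to the spine. Per-slice frames are
aggregated by component-wise median over the middle run, which is
robust to individual slices where detection fails (those are skipped
and flagged, never fatal unless all fail).

The two biopsy disks sit at `center ± k_offset * chest_scale` along
the axis perpendicular to the spine-breastbone axis, with radius
`k_radius * chest_scale`; the same disk is used on every slice of the
run, making each ROI a cylinder. Scaling with `chest_scale` (the
breastbone-spine distance) makes placement invariant to animal size
and scan resolution. The defaults `k_offset = 0.55`, `k_radius = 0.28`
are free parameters fixed once by calibrating the mean lung-volume
coverage of the two biopsies to 14% (the design target, with an
accepted band of ±3 percentage points) on the default phantom cohort,
and then frozen in the configuration. A disk that would exit the slice
is shrunk to fit (with a warning) rather than clipped, so the ROI
volume stays well defined. Side naming follows the animal's anatomy
under the convention image-left = animal-right; `side_flip` reverses
it.

## The synthetic phantom

`generate_phantom()` builds a posed, noisy thorax: an elliptical
soft-tissue body, two aerated lungs (left single-lobed and smaller, as
in the mouse), a trachea branching into two main bronchi that reach
into the cranial third of the lungs, a sternum anterior and a
vertebral column posterior on the midline, air around. All geometry is
specified in fractions of the stack extent, so a 256- or 128-voxel
phantom is proportionally identical to the default 512 x 512 x 512 at
0.04 mm. Intensities are Gaussian per compartment — air 300 ± 50,
airway lumen 350 ± 50, parenchyma 1250 ± 120, soft/dense tissue
2250 ± 120, bone 3200 ± 150 — chosen to sit inside the aerated
(1000-1500) and dense (2000-2500) ranges the features are defined
over; only those ranges are anatomically anchored, the means and SDs
are the generator's own choices.

Disease transforms act on lung voxels only:

* **fibrosis**: spherical blobs (radius 3-8 voxels) are added until a
  fraction `0.6 * severity` of lung voxels is replaced by draws from
  the dense-tissue distribution. Blob replacement (rather than a
  global shift) is deliberate: it produces the second histogram peak
  and exercises the AUC ratio the way real fibrotic lungs do.
* **emphysema**: the parenchyma mean drops by `250 * severity`,
  shifting the histogram left.
* **LPS**: no voxel-level change — an acute inflammation model should
  read as a negative control for densitometry.

Slice classes derive from the lung extent: lung-bearing slices split
30% / 30% / 40% into top/front, middle, bottom/rear (the split is
chosen so the middle run is 60-100 slices at full scale — about 77 on
the default geometry); pre-lung slices containing airway are
`only_bronchi`. The lungs' lateral separation drifts slightly along
the cranio-caudal axis and the bronchi only reach the cranial third,
so the classes are geometrically identifiable from slice content —
without this the front and rear thirds of an ellipsoidal lung would be
indistinguishable by construction.

The pose (in-plane rotation U(-10, 10) degrees, translation U(-15, 15)
voxels at full scale, scaled with the field of view so small phantoms
keep the same relative positioning tolerance) emulates variation in
animal placement. Geometry is evaluated on inverse-posed coordinates,
so masks, landmark boxes and intensities move rigidly together, and
the truth pose is recoverable from the landmark boxes to within the
rasterization.

Simulated covariates link severity to the readouts used for
validation: Ashcroft score `round(7 * severity) + N(0, 0.5)` clipped
to [0, 8] (fibrosis arms), mean linear intercept
`40 + 60 * severity + N(0, 3)` um (emphysema arms), and FVC
`1.2 - 0.6 * severity + N(0, 0.05)` ml.

What the phantom does *not* emulate: lobe boundaries, vessels, cardiac
and breathing motion, beam hardening, scanner noise correlation, and
the anatomical variability of real mice. Passing phantom tests
demonstrates the pipeline's internal consistency — placement
equivariance, feature correctness, the truncation artifact, correct
correlation signs — not its accuracy on in-vivo data, which requires
real labeled scans.

## Trainable components

The slice classifier and the semantic segmenter are pluggable. The
paper-style configurations (224 x 224 byte input with ±10 degree /
4 px / 5% augmentation, momentum 0.9, weight decay 0.001, learning
rate 1e-3 to 1e-5 over 150 epochs for classification; 512 x 512 input,
±5 degrees / 10 px, momentum 0.99, 5e-4 to 3e-5 over 2500 epochs for
segmentation) are recorded in `classifier_config()` /
`seg_train_config()` so a convolutional back end can consume them.
The built-in defaults are deliberately lightweight and CPU-friendly:

* `train_classifier()` fits a random forest on engineered per-slice
  features (compartment area fractions, aerated-tissue centroid
  geometry, lateral lung separation) computed from the preprocessed
  byte image. It trains in seconds on ~100 slices per class from
  phantoms and exceeds 90% held-out slice accuracy.
* `train_segmenter()` fits a classification tree on per-voxel features
  (intensity, 3 x 3 neighbourhood mean/SD, in-body flag) with
  stratified subsampling so the rare airway and bone classes keep
  support. It exceeds 90% per-class voxel agreement on held-out
  phantoms.

Both persist to self-describing model files (config plus FNV-1a config
hash) and reload to identical predictions. Oracle variants backed by
phantom ground truth (`oracle_classifier()`, `oracle_segmenter()`)
make downstream stages exactly reproducible in tests. The `ignore`
label is reserved for trainable segmenters' uncertain pixels; the
rule-based reference never emits it.

## The legacy mode

`segment_threshold_legacy()` reproduces the behaviour this approach
replaces: in-body voxels in the intensity window (700, 1850], the two
largest 3D connected components, and in-plane holes of up to 3 voxels
filled. The intensity truncation is absolute — hole filling never
readmits voxels above the limit — because the truncated histogram
support is the defining artifact: on a severity-0.8 fibrosis phantom
the legacy set misses over 90% of the dense fibrotic voxels, and its
histogram has zero mass above 1850, while the biopsy-based MLA keeps
tracking severity.

## Numerical choices and edge cases

* Byte conversion rounds half up, so the midpoint maps to 128 exactly
  and tests are bit-exact; it clips outside the window.
* The default HU calibration (air 0, water 2330) is the unique linear
  map satisfying air = -1000 HU and raw 1850 = -206 HU; scanners
  should override it via `voxel_calibration()`.
* Middle-run selection applies majority smoothing (window 5, ties keep
  the centre label) before taking the longest run; equal-length runs
  resolve toward the stack centre, where the middle of the lung
  anatomically sits.
* Histogram values outside the range are clipped into edge bins with a
  warning rather than dropped, preserving count conservation.
* Degenerate inputs fail loudly: empty voxel sets, constant samples
  (zero variance), single-class training sets, stacks with no middle
  slices, and slices without two bone components all raise explicit
  errors.

## Validation problem sizes

The packaged tests validate the full pipeline at proportionally scaled
geometry: 128-voxel phantoms for unit and cohort tests, 192 for pose
equivariance, 256 for the 10-animal coverage cohort and the legacy
truncation check, and one full-scale 512 x 512 x 512 phantom for the
stack-geometry and middle-run checks. The acceptance script
(`scripts/acceptance.R`) recomputes the biopsy coverage on a fresh
10-animal control cohort at 256-voxel scale; placement is scale-free,
so coverage is invariant to this choice.

## Known limitations

* The phantom's geometric regularity makes landmark detection easier
  than on real scans; the rule-based detector is a reference
  implementation, and real deployments should train the pluggable
  detection stage.
* The rule-based reference segmenter labels *all* in-body
  non-airway/non-bone voxels as tissue, so its `whole_lung` scope
  includes mediastinal soft tissue; use a trained or oracle segmenter
  when the whole-lung scope matters.
* Densitometry of severely fibrotic lungs is intrinsically harder:
  FWHM and mode are flagged, and MLA and the AUC ratio are the robust
  readouts.
* Correlations reported by `correlate()` are descriptive (raw Pearson
  r and two-sided p, pairwise deletion, no multiplicity correction).
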