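---
title: "Dose-prediction-based technique selection: models, engines and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-prediction-based technique selection: models, engines and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-breast radiotherapy is planned either with opposed tangential
fields (3D-CRT) or with inverse-optimized modulated fields (IMRT). IMRT
usually buys better target conformity and lower organ-at-risk (OAR)
peak doses at the price of a larger low-dose bath and more planning and
delivery effort, so the clinically preferred policy is *3D-CRT by
default, IMRT only when the conformal plan cannot meet the OAR
constraints*. Whether a given anatomy can meet them is only known after
a plan has been made — which is exactly the effort one wants to avoid.

`rtdecide` implements a decision-support pipeline around a learned dose
predictor: a 2D U-Net regresses the per-slice absolute dose
distribution of *both* candidate techniques directly from the CT slice
and the structure masks; dose–volume histogram (DVH) metrics are
extracted from the predicted volumes; and the clinical constraint set —
ipsilateral lung V20Gy < 30 %, heart V25Gy < 10 %, mean heart dose
< 3 Gy, all strict — picks the technique. Everything is exercised
end-to-end on a synthetic phantom cohort, because no clinical cohort is
distributed with the package.

## The dose regressor

The network is a 2D encoder–decoder with skip connections
(`dosenet_config()`): `depth` resolution levels, `base_filters` filters
at the top (doubled per level), depthwise-separable (Xception-style)
convolutions in the encoder blocks, full 3×3 convolutions in the
bottleneck and decoder, 2×2 max-pooling, nearest-neighbour upsampling,
and a 1×1-convolution + ReLU head so predicted dose is non-negative.
The published architecture this follows is cited only by style, not as
a full recipe; the default (depth 4, 32 base filters, separable
encoder) is therefore a documented choice and fully configurable.

Input is a 6-channel slice: window/level-normalized CT plus one binary
channel each for body, ipsilateral lung, heart, breast PTV and nodal
PTV (all-zero when absent, keeping the channel count constant). A
single-channel combined-label mask would also be compatible with the
training loop; one-channel-per-structure was chosen because it removes
label-encoding ambiguity at organ boundaries.

Training (`dosenet()`) minimizes voxel-wise mean-squared error on
absolute dose (Gy) with Adam — learning rate 0.001, β₁ = 0.9,
β₂ = 0.999 — for exactly 20 epochs, batch size 16 (batch size is not
specified by the source protocol; 16 is the package default). There is
no validation split or early stopping, deliberately. Fine-tuning
(`init =`) starts from a source model's weights and retrains **all**
layers; the optimizer state restarts, which is the standard behaviour
when continuing training in a new session. Since no deep-learning
framework is available in this R stack, the forward pass,
backpropagation and Adam loop are implemented in compiled code inside
the package; computation is single precision (the customary choice for
network training) and a session is deterministic given the seed on a
given platform, though bit-reproducibility across BLAS builds is not
promised — evaluation therefore uses tolerances, never bit equality.

Weight initialization is He-normal (`sd = sqrt(2/fan_in)`), biases
zero, drawn from R's RNG under the control seed.

Cross-validation (`run_cross_validation()`) is patient-level: whole
cases are assigned to folds, each fold's model never sees its test
cases' slices, and every case receives exactly one out-of-fold
predicted volume. Slice-level splitting would leak near-duplicate
neighbouring slices across the split and is structurally impossible
here. The four training regimes of the study design map onto arguments:
ModelA/ModelD train from scratch (`init = NULL`), ModelB/ModelC
fine-tune from ModelA weights (`init = modelA`); the constructor
enforces these pairings when a regime name is given.

## Data preparation

`assemble_slices()` reproduces the preparation chain: each axial slice
is cropped to the tight bounding box of the body mask plus a margin
(default 2 voxels — the margin is not specified upstream and is
configurable), then nearest-neighbour resampled to a fixed square
(default 128×128; the reduced experiments below use 64×64). The
nearest-neighbour rule is pixel-centre aligned:
output pixel *i* (0-based) copies source pixel
`floor((i + 0.5) * n_src / n_out)`; an output centre exactly midway
between two source centres resolves to the larger index. Aspect ratio
is *not* preserved — cropped boxes of varying shape are stretched to
the square — so the crop box and original shape are stored with every
slice and `restore_dose()` inverts the mapping for volumetric DVH
evaluation. DVH metrics are computed on the original grid after
back-mapping (a bounding-box crop/resample on the resampled grid is a
config choice away, but the original grid is the default because the
constraint thresholds refer to true organ volumes). Cropping is
per-slice, then resampling, matching the single-slice nature of the
network input.

Dose renormalization (`renormalize_dose()`) rescales any plan to the
reference prescription of 2 Gy × 25 fractions = 50 Gy.

CT normalization uses window 400 HU / level 40 HU mapped to [0, 1] — a
soft-tissue window; also a package default, not a value stated
upstream.

## The synthetic phantom cohort

`generate_case()` builds pseudo-3D thorax phantoms: an elliptical body
with two lungs, a heart, a breast mound carrying the PTV on the
configured side, and an optional nodal PTV on superior slices;
cross-sections vary slowly along the axial direction so volumetric
DVHs are meaningful while the network stays 2D. CT-like intensities are
≈ 0 HU soft tissue, −700 HU lung, −1000 HU air with mild Gaussian
noise — enough structure for a usable intensity channel without
modelling imaging physics. Two institutional flavours differ in slice
thickness (3.75 mm vs 3 mm), node-positive fraction (0.75 vs 0.36,
following the published cohort tables) and complexity mix.

Anatomical complexity is driven by drawn covariates, recorded on each
case so ground-truth difficulty is known: heart proximity (0 → ≈ 44 mm
chest-wall gap, 1 → ≈ 4 mm), PTV size, chest curvature, laterality.
The complexity mix of the real institutions is not quantified anywhere;
the default uniform ranges are package choices stated in
`cohort_spec()`, set once so that roughly three quarters of a default
`inst2` cohort passes the 3D-CRT constraints — the same order as the
30-patient validation cohort the decision framework was originally
scored on (23/30 conformal).

### Analytic dose engines

The paired dose engines are geometric surrogates, not transport
calculations — deterministic, desk-scale, and sufficient to create
learnable CT→dose structure with the right qualitative contrasts.

**3D-CRT** (`simulate_dose_3dcrt()`): the beam corridor is the slab
between the two tangents fitted to the PTV's projection onto the
tangential axis (margin 8 mm). With `ssd` the signed distance to the
slab boundary (negative inside) and `u` the along-beam coordinate:

    D(x) = Rx · max( logis(−ssd/2.5 mm) · [1 + 0.04 sin(2πu/90 mm + φ)],
                     0.04 · exp(−max(ssd,0)/25 mm) )

inside the body, zero outside, capped at 1.25 Rx. The first term is the
corridor plateau with a sigmoidal penumbra and a wedge-like ripple; the
second a small scatter bath. OAR dose consequently grows monotonically
with the geometric overlap between corridor and organ — the property
the selection problem hinges on.

**IMRT** (`simulate_dose_imrt()`): the maximum of (i) a conformal
high-dose region hugging the PTV (sigmoid in the Euclidean distance
outside the PTV, margin 7 mm, penumbra 2 mm, ripple 1.5 %), (ii) an
entrance/exit bath along the *same* tangential corridor
(0.14 Rx · exp(−ssd⁺/60 mm) — modulated tangential incidences still
deposit entrance dose), and (iii) an isotropic scatter term
(0.05 Rx · exp(−d_PTV/50 mm)); all multiplied by an optimizer-like
heart avoidance factor that suppresses up to 85 % of dose over the
heart *wherever that does not compromise PTV coverage* (the suppression
is gated off within ≈ 10 mm of the PTV). Distance maps come from
`EBImage::distmap`.

These constants were chosen analytically so the documented paired
contrasts hold by construction and are then verified per case in the
test suite: equal-or-better PTV homogeneity, equal-or-lower heart V25
and lung V20, equal-or-larger 5 Gy bath under IMRT. One consequence is
deliberately realistic: anatomies with the heart almost abutting the
chest wall can fail the 3 Gy mean-heart constraint under *both*
techniques; the framework then recommends IMRT with
`needs_review = TRUE`.

Slices without any PTV receive the nearest PTV-bearing slice's pattern
attenuated exponentially (15 mm length constant); a case with no PTV at
all receives zero dose. Ground-truth labels (`generate_cohort()`) apply
the constraint set to the *simulated* 3D-CRT dose — the same rule an
observer applying the clinical criteria to reference plans would use —
so the oracle end-to-end run of the framework reproduces the labels
exactly, which is itself a test.

What the phantoms do **not** emulate: scanner artefacts, contouring
variability, field-in-field segments, wedges or MLC sequences,
breathing motion, and real anatomical diversity. Passing tests on
phantoms therefore demonstrates the *pipeline* — learnability,
metric extraction, constraint logic, transfer behaviour — not clinical
dose-prediction accuracy.

## DVH engine and evaluation

`compute_dvh()` bins cumulative curves at 0.1 Gy by default, but all
headline metrics (`extract_metrics()`) bypass binning and use exact
voxel statistics: Dmean is the mean voxel dose, Vx the exact voxel
fraction at-or-above threshold, and D95 the 5th percentile of voxel
doses with linear interpolation between order statistics (the estimator
is not defined upstream; this choice is documented and covered by a
brute-force oracle to within one interpolation step). Volumes count
voxel centres; there is no partial-volume weighting. An empty structure
is reported *absent* (`NA` metrics), never as zero dose — and cohort
tables drop such cases from their cell rather than zero-filling.
Both V95 % and D95 % are computed for the PTV, since the source
protocol's text and tables differ on which one is reported.

Metric comparison follows the published convention: dose metrics as
`(clinical − predicted)/prescription × 100`, volume metrics as the
direct difference in percentage points.

Spatial agreement uses isodose-volume Dice (`dsc_curve()`): thresholds
default to 5–100 % of prescription in 5 % steps (the exact grid used in
the source figures is unstated), computed volumetrically per case. Two
empty volumes — common above the hottest isodose — score DSC 1.0:
agreement on absence. The 30–70 % band mean is the headline summary.

## The decision rule

`recommend()` is total and deterministic: 3D-CRT whenever its predicted
plan passes all three OAR constraints; otherwise IMRT; when both fail,
IMRT with a review flag (the escalation arm preserves clinical
oversight — the source rule is silent on this case). PTV metrics are
carried in the audit output but never gated on, mirroring the
OAR-constraint-driven protocol. Validation uses a 2×2 confusion matrix
with **3D-CRT as the positive class** — the assignment is pinned down by
the published metrics themselves (recall 47.8 % = 11/23 only holds with
3D-CRT positive) — and accuracy/recall/precision/F1 in percent, with
zero-denominator metrics reported as undefined rather than zero.

## Problem sizes and numerical choices

The reference experiments in the test suite and the acceptance script
use reduced sizes chosen as the package's study conditions: phantoms of
10 slices on an 80×80 grid (4 mm pixels), slices prepared at 64×64, a
reduced network (depth 3, 16 base filters), 20 epochs; the
cross-validated 3D-CRT cohort has 40 cases with k = 4 (24 with k = 3 in
the acceptance script), the transfer-learning target cohort 15 cases
with 10/5 train/test splits over three seeds. On these sizes the mean
out-of-fold 30–70 % isodose DSC is ≈ 0.87–0.9, comfortably above the
0.8 working threshold, and fine-tuning from the conformal-trained model
meets or beats from-scratch training on the small IMRT cohort.

Other numerical conventions: grids are row-major and 0-based with
half-open crop boxes; dose maps are clamped to [0, 1.25 Rx] by the
engines and at 0 by prediction back-mapping; max-pooling ties keep the
first (top-left) argmax; the training loss reported per epoch is the
running MSE over that epoch's forward passes.

## Known limitations

* The dose engines are geometric: no heterogeneity corrections, no
  deliverability, no wedge or MLC modelling. They are a scaffold for
  the pipeline, not a planning system.
* Fine-tuning restarts the Adam state; very short fine-tunes behave
  slightly differently from continuing an uninterrupted run.
* Single-precision training means models trained on different BLAS
  builds can differ in low-order bits; all assertions are tolerance
  based.
* DICOM import/export is out of scope here; the cohort container is an
  RDS-per-case directory with a TSV manifest.
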