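---
title: "Methods: ultrasound radiomics for sentinel-node status prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasound radiomics for sentinel-node status prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnradiomics)
```

## The problem and the modeling approach

In breast cancer patients who are clinically node-negative, the axillary
nodal status is usually established intraoperatively (sentinel-node biopsy
with a molecular assay), an invasive and costly procedure in a population
where roughly 15% turn out positive. `slnradiomics` implements a
non-invasive alternative pipeline that predicts the binary nodal status from
two preoperative sources: the primary-tumor ultrasound image acquired at
diagnosis, and twelve routine clinical/histopathological variables.

The pipeline has five stages:

1. **Image cleanup.** Caliper markers left on the image at screening are
   removed by inpainting (see *Numerical choices*).
2. **ROI construction.** From a seed point inside the lesion, seeded region
   growing segments the hypoechoic intra-tumoral region; morphological
   dilation by 2 cm produces the combined ROI; the peritumoral ROI is their
   set difference; the original ROI is the bounding rectangle of the
   combined mask plus a margin. Peritumoral tissue is included deliberately:
   the tumor–normal interface is a site of proliferation and angiogenesis,
   and its texture carries predictive signal.
3. **Radiomics.** Each ROI is gray-quantized and described by 134 named
   texture features from four matrix families: gray-level co-occurrence
   (GLCM), run-length (GLRLM), size-zone (GLSZM) and neighborhood gray-tone
   difference (NGTDM), with GLCM/GLRLM computed in the four in-plane
   directions (0°, 45°, 90°, 135°).
4. **Learning.** One stratified 80/20 hold-out split is shared by all
   models. The clinical model is an RBF-SVM on the encoded clinical
   variables. Each radiomic model first runs genetic-algorithm (GA) feature
   selection inside a leave-one-out cross-validation (LOOCV) loop on the
   training set and keeps the features selected in at least 50% of the
   rounds, then fits an RBF-SVM on that subset.
5. **Ensembling and evaluation.** Soft voting averages the calibrated
   scores of the clinical model and each radiomic model, giving eleven
   models in all (1 clinical + 5 radiomic + 5 soft-voting). All are
   evaluated on the same test set by AUC, and by accuracy / sensitivity /
   specificity at a decision threshold equal to the training-set positive
   prevalence, with percentile-bootstrap 95% CIs (200 rounds) and a
   label-permutation p-value for AUC.

Because no patient cohort is distributed with the package, a first-class
synthetic-data module generates ultrasound-like phantom images and clinical
tables with controllable class effects, so that every stage above is
exercised end to end by the test suite.

## The synthetic cohort: what it emulates and what it does not

`gen_cohort()` emulates the published study population: 142 patients, 115
node-negative and 27 node-positive (prevalence 19%), each with one
grayscale ultrasound frame containing a hypoechoic lesion, optional caliper
markers, and a 12-variable clinical table whose marginals default to the
published cohort description (median age 60 [48, 69]; diameter classes
T1a/T1b/T1c/T2 at 8.5/29.6/40.1/21.1%; ~9% missing age, under 1.5% missing
elsewhere; and so on). Labels are drawn to hit the requested prevalence
exactly (`round(n * prevalence)` positives).

**The image model.** A phantom is a two-region mean map — a darker
(hypoechoic) lesion ellipse on a brighter background — multiplied by a
speckle field: a unit-mean gamma texture (shape 4), lightly Gaussian-smoothed
(sigma 0.7 px) to give the speckle a grain, with `speckle_scale`
controlling its amplitude. With `speckle_scale = 0` the phantom is exactly
piecewise constant, which the tests exploit.

**How the class effect enters.** For positive patients the lesion *and* a
surrounding ring (so that intra-, peri- and original-ROI models can be
differentially informative) receive two texture shifts scaled by
`class_effect`: the speckle amplitude is inflated by `1 + class_effect`,
and the speckle correlation length is increased (the smoothing sigma becomes
`0.7 * (1 + class_effect)`), making the grain coarser. The second channel
matters: the feature extractor quantizes each ROI over its own gray range,
and an amplitude-only shift is a linear rescale of in-mask grays that
quantization removes entirely — a coarseness shift survives it. This is a
deliberate design choice so that planted texture signal is actually
recoverable by quantized texture statistics.

**Clinical class effect.** `clinical_effects` is one standardized effect
size: positives have age and ki67 shifted upward by that many within-class
standard deviations, and the multifocality and angioinvasion odds tilted by
the same amount on the logit scale — the variables reported as
class-associated in the emulated cohort.

**What passing tests do not show.** The phantom is not a physical
ultrasound simulation: there is no beam geometry, attenuation, shadowing,
or operator variability, lesions are single ellipses, and clinical
variables are drawn independently of each other given the class. Green
tests therefore demonstrate that the *pipeline machinery* is correct and
that planted signal of a known kind is recovered — not that the method
attains any particular performance on real patients. The emulated study's
reported performance is not reproducible here because its patient data are
not deposited; the package's acceptance checks are structural and
behavioral instead.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `ring_mm` | 20 | mm | the 2 cm peritumoral dilation prescribed by the emulated protocol |
| `box_margin_mm` | 5 | mm | margin of the original-ROI bounding box; the protocol never defines it, so it is explicit and configurable |
| `tolerance` | 25 | gray levels | region-growing admission band; recovers phantom lesions at Dice ≥ 0.9 up to moderate speckle |
| `levels` | 32 | bins | gray quantization; standard radiomics practice, configurable |
| `pixel_spacing` | 0.5 | mm/px | typical breast-ultrasound scale; the protocol states none, so it is an explicit stand-in |
| `cutoff` | 0.5 | fraction | LOOCV selection-frequency rule: keep features selected at least 50% of the time |
| SVM `cost`, `gamma` | 1, 1/p | — | defaults on standardized features (the protocol states none) |
| GA population/generations | 30 / 20 | — | wrapper-selection defaults; fitness = internal CV AUC − 0.002 per active feature |
| `bootstrap_rounds` | 200 | — | the published CI round count |
| threshold | train prevalence | — | prevalence thresholding; computed on the training set only to avoid test leakage |

The 134-feature catalogue is itself data: a JSON manifest (22 GLCM
statistics × 4 directions + 7 GLRLM × 4 + 13 GLSZM + 5 NGTDM) that can be
replaced by any breakdown totalling 134, since the emulated study never
enumerates its feature set.

## Numerical choices and degenerate inputs

* **Inpainting** is a fast-marching fill: unknown pixels adjacent to known
  data are filled layer by layer, each as a convex combination of its known
  8-neighbors with weights that down-weight neighbors lying across the
  local gradient direction (estimated from a smoothed copy), so edges are
  transported into the hole rather than blurred across it. It is a
  practical realization of coherence-guided fill, not a PDE transport
  solver; the guaranteed contracts are bit-identity outside the mask and
  boundedness by the known neighborhood values. A mask covering the whole
  image is an error (no boundary data).
* **Region growing** admits frontier pixels best-first (smallest absolute
  difference from the running region mean), updating the mean after every
  admission, so the result does not depend on neighbor enumeration order;
  growth stops when no frontier pixel is within tolerance. 8-connectivity
  by default (4 as an option); the grown region is hole-filled. Seeding on
  a marker pixel is refused with advice to inpaint first.
* **Dilation** uses an exact discrete Euclidean disc of radius
  `round(radius_mm / spacing)` pixels; radius 0 is the identity. The
  emulated protocol's text calls this step an "erosion" while describing an
  expansion; it is implemented as dilation, which the ROI nesting
  (intra ⊆ combined) requires.
* **Quantization** uses equal-width bins over the in-mask range; a constant
  region maps to bin 1. Coordinates are row-major and 0-based; boxes are
  half-open.
* **Degenerate statistics** (empty pair sets, zero denominators such as
  NGTDM coarseness on a constant region) return 0 rather than non-finite
  values, so feature vectors are always finite.
* **Ties and seeds.** Imputation donor ties break by lowest reference row
  index; AUC uses midranks; LOOCV round *i* reseeds the GA as
  `base_seed + i`; every stochastic stage takes an explicit seed and the
  full pipeline is bit-reproducible for a fixed configuration.
* **Imputation** encodes ordinals as ranks and nominals as one-hot columns,
  z-scales everything, and measures Euclidean distance over the coordinates
  the incomplete patient observed; every missing cell is copied from a real
  complete-case donor row. New patients can be completed against a frozen
  reference cohort.
* **Score calibration.** SVM decision values are mapped to [0, 1] by a
  sigmoid fitted on internal training folds (Platt scaling). This is what
  makes score averaging (soft voting) and prevalence thresholding
  meaningful; the emulated study does not state its calibration method.
* **Empty selections.** If no feature reaches the frequency cutoff, the
  runner falls back to the features at the maximum observed frequency; in
  the cutoff-scan (`frequency_curve()`) an empty cutoff is flagged and not
  computed, to keep the reporting honest.

## Open design points resolved here

* Whether the 2 cm is a radius or a diameter is unstated; it is implemented
  as the dilation radius.
* Whether the prevalence threshold uses cohort or training prevalence is
  unstated; the training set is used to avoid test leakage.
* The selection-frequency/AUC trade-off curve is reproduced as a *reporting*
  device (`frequency_curve()`), not as a cutoff-selection rule, because
  choosing the cutoff on test AUC would leak test information.
* AUC significance asterisks are computed by a label-permutation test
  (≥1000 rounds) against the chance null; the original significance
  procedure is unstated. Bootstrap CIs use stratified percentile resampling.

## Problem sizes used by the tests and acceptance script

The suite exercises the full pipeline at desk scale: phantoms of 48–128 px,
cohorts of 12–142 patients, GA populations of 6–10 over 3–6 generations
with 3-fold internal CV for the simulation-heavy properties, and the
package defaults (population 30, 20 generations, 5-fold CV) for real use.
Calibration properties use 200 simulated null cohorts of 142 patients
(false-flag rate ≈ 5%), 20-seed recovery runs for GA selection, and
20-seed ensemble simulations at n = 60 with strong, comparable clinical and
radiomic signal. All of these sizes are the package's own choices for fast,
stable simulations; the statistical contracts they check are
size-independent.

## Known limitations

* Single lesion per image; no automatic seed detection (the lesion center
  is an input, as in the emulated workflow where a radiologist delimited
  the ROI).
* 2-D only; no DICOM writing; no wavelet/shape/first-order intensity
  features; IBSI-style names are used but no IBSI certification is claimed.
* The GA is a stochastic wrapper: selection frequencies stabilize only
  through the LOOCV aggregation, and with very small training sets the
  internal CV folds are coarse.
* Bootstrap CIs are percentile CIs of the resampled point estimator; with
  tiny test sets (a handful of positives) they are wide and discrete.
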