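---
title: "Virtual double staining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual double staining: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: what is being
measured, how each stage works, which knobs matter, what the synthetic
generator does and does not emulate, and where the genuinely open design
choices were settled.

## The measurement problem

Chromogenic in situ hybridization (ISH) localizes a transcript — here a
microRNA that concentrates in the activated fibroblast stroma of oral
squamous cell carcinomas — as a blue NBT/BCIP precipitate on a tissue
section. The biological question is compartment-specific: signal in the
*stroma* carries prognostic information that signal in the tumor
epithelium does not. A single section cannot answer this, because the ISH
stain does not say which pixels are tumor epithelium. The solution is
*virtual double staining*: a serial section is stained for pan-cytokeratin
(brown DAB), the two sections are registered, and the cytokeratin-derived
tumor mask is transferred onto the ISH section. Within a manually drawn
region of interest (ROI, the tumor area), pixels then split into a tumor
compartment and a stroma compartment, and the stromal score is

$$\mathrm{TBS} = A_{\mathrm{blue}} \times \bar{I}_{\mathrm{blue}},$$

the number of chromogen-positive stromal pixels times their mean blue
intensity. `TBT` is the same product in the tumor compartment, and `TSA`
(total stroma area) is the stromal pixel count. Patients are split into
tertiles of TBS and the tertiles are compared by Cox
proportional-hazards regression on disease-free survival (DFS, months
from operation to recurrence), alongside the standard clinical factors.

## Intensity is optical density

"Blue intensity" is deliberately defined as the blue-chromogen *optical
density* (OD) obtained by stain unmixing, not as inverted 8-bit
brightness. OD is linear in chromogen amount (Beer–Lambert), so
`area x mean OD` equals the integrated chromogen OD over the positive
pixels — TBS becomes an estimate of total chromogen mass, with an exact
algebraic identity the tests exploit:
`tbs == sum(blue_od[positive & stroma])`. The convention is recorded in
the score outputs. The conversion is `OD = -log10((I + 1)/256)` per
channel; the `+1` offset keeps black pixels finite and is bit-exactly
inverted by the renderer, so rendering and re-reading an image is
lossless for all 256 levels.

Unmixing itself is a least-squares projection of each pixel's 3-vector OD
onto at most three unit stain vectors (Moore–Penrose pseudo-inverse,
negative concentrations clamped to zero). The DAB/hematoxylin vectors are
the standard Ruifrok–Johnston values. No standardized colorimetry exists
for NBT/BCIP or nuclear fast red, so the package defines fixed default
vectors for the ISH pair (a blue precipitate absorbs red and green; a red
counterstain absorbs green and blue), shares them with the synthetic
renderer, and lets users supply measured vectors as JSON. Blind
stain-vector estimation (Macenko-style) is intentionally out of scope.

## Thresholding

The original workflow set chromogen thresholds by eye in a commercial
package; the thresholds themselves were never reported. The package
replaces them with Otsu's method on the chromogen OD histogram — a
deterministic, parameter-free surrogate — and records the chosen OD in
the output metadata. A fixed OD threshold can be supplied instead when a
laboratory has calibrated one. Thresholding is monotone (raising a fixed
threshold never adds positive pixels) and involves no randomness. A
constant map has no Otsu threshold and is rejected with advice to use a
fixed value. Optional small-object removal exists (`min_object_area`) but
defaults to off, since the original method describes no morphological
cleanup.

## Registration

Serial sections are cut at most a few micrometers apart, so their shared
architecture differs mainly by placement on the slide: the package's
transform family is translation + rotation + isotropic scale
("similarity", the default; translation-only, rigid, and full affine are
options, shear being physically unmotivated). The similarity metric is
normalized cross-correlation (NCC) of the two *total OD* maps (sum of the
three channel ODs), which is stain-agnostic: the two sections carry
different chromogens, and raw RGB correlation would be dominated by the
color difference rather than the shared tissue density.

The optimizer is deterministic by construction — a three-level image
pyramid (block-mean downsampling), an exhaustive multi-start grid over
rotations (±6° in 2° steps), scales (0.95/1.00/1.05) and integer shifts
at the coarsest level, then Nelder–Mead refinement at every level with
fixed ordering. No seeds are involved; rerunning a registration gives the
same answer bit for bit. The returned score is never below the NCC of the
unaligned pair (the identity is always a candidate), and blank tiles
(total OD below 0.1 everywhere) are rejected as "no tissue signal".
Deformable registration is deliberately absent: residual local error is
absorbed by the area-level scores, and the synthetic benchmark shows the
area scores tolerate it.

On the synthetic benchmark (50 misalignments drawn across ±20 px, ±5°,
±5% scale), the test suite requires recovery within 0.5 px, 0.2° and
0.5% scale in at least 95% of trials. Masks are
transferred with nearest-neighbor resampling so they stay binary; pixels
mapped from outside the source are background.

## Compartments and scores

`build_compartments` enforces the set algebra by construction: the tumor
compartment is the warped DAB mask intersected with the ROI, the stroma
is the ROI minus the tumor, so `tumor ∪ stroma = roi` and
`tumor ∩ stroma = ∅` hold identically. The mean OD over an empty positive
set is defined as zero, making `TBS = 0` exactly when no positive stromal
pixel exists (ten of the 86 patients in the motivating study showed
little to no stromal signal, so the zero case is a real one). Scores are
reported in pixel units; physical units were never stated for the
original quantities, and a µm² scale can be applied downstream from image
metadata if known.

## The synthetic image generator

The generator exists so that every pipeline stage has exact ground truth.
One scene is drawn per sample on a padded canvas: an inset rectangular
ROI; elliptical tumor nests (unions of random ellipses — the island
morphology of epithelial nests with trivially computable masks) covering
a configured fraction of the ROI; clumpy blue-positive patches obtained
by thresholding a smoothed Gaussian field at the exact per-compartment
positive fraction; per-pixel blue OD drawn as Gamma(shape 16, scale
0.028) on positive pixels (positive, right-skewed, concentrated enough
that Otsu separates it cleanly from background); DAB OD on nest pixels;
and a *shared* nuclear-counterstain texture with structure at three
spatial scales (σ = 1.2, 2.5 and 8 px) plus a darker-in-nests term, since
epithelial nests are cell-dense under any counterstain. The scene is
rendered twice through Beer–Lambert mixing with the package's default
stain matrices: directly as the IHC tile, and warped by the configured
misalignment (default: 6.5/−4.25 px shift, 1.5° rotation) as the ISH
tile, with additive RGB noise (sd 2 levels).

Ground truth (masks, per-pixel blue ODs, and the full score panel) is
taken from the drawn fields *before* rendering, so `tbs_true` is an exact
sum the pipeline can be held to. The multi-scale shared texture is what
makes NCC registration well-posed: its fine component pins translation
and rotation to subpixel accuracy, its coarse component survives pyramid
downsampling, and its amplitude is chosen large enough that the
(necessarily uncorrelated) chromogen patterns of the two stains do not
bias the optimum.

What the generator does **not** emulate: real serial sections are
different physical slices, so their nuclear texture is only locally
similar, not shared pixel-for-pixel as here; there is no nuclear
morphology, no scanner illumination field, no out-of-focus blur, no
whole-slide pyramid, and no deformation between sections. Passing the
synthetic benchmark therefore demonstrates the pipeline's correctness
under its own assumptions (affine misalignment, known stain vectors,
separable chromogen), not its robustness to scanner artifacts — the
registration tolerance on real material must be established per
laboratory.

Tile size defaults to 160×160 px. This is small for histology but is the
deliberate unit of the package's own analyses: it keeps a full 20-pair
benchmark plus a 50-trial registration sweep fast while leaving every
statistic meaningful, and nothing in the code assumes the default size.

## The cohort generator

Survival cohorts are drawn under an exponential-baseline proportional
hazards model; event times in months, administrative censoring at 120
months plus exponential dropout (rate 1/240 per month). The baseline rate
is calibrated by root finding so the expected event fraction matches a
target, default 0.33 — the motivating study does not report its number of
recurrences, and a third of patients relapsing within follow-up is
consistent with its relapse-site tabulation; the value is configurable.
The stromal score follows a mixture of a point mass at zero (weight
10/86) and a lognormal, mirroring the observed score distribution.

Covariate prevalences default to the published 86-patient margins
(e.g. 21/86 node-positive, 15/86 perineural invasion). Stage is *not*
drawn independently: TNM-style, nodal spread or a large primary implies
stage III/IV. Stage is therefore marginally prognostic whenever nodal
status is, but carries no conditional effect — exactly the situation in
which backward elimination should admit stage as a candidate and then
remove it, which is the behavior the tests demand.

Three presets decide which covariates carry the hazard:

* `univariate_tertile` — hazard depends only on the tertile index of the
  score, default upper-vs-lower HR 2.7;
* `univariate_single_factor` — one binary factor, default nodal status at
  HR 3.0;
* `multivariate` — conditional HRs 1.6 (per tertile step), 2.1
  (perineural), 2.5 (nodal status).

The univariate presets exist because Cox hazard ratios are
non-collapsible: the marginal HR of a factor in the multivariate
generator is not the configured conditional one, so univariate recovery
must be tested against a generator whose hazard depends on that factor
alone. A deliberate proportional-hazards violation is available
(`ph_violation`): the covariate's log hazard ratio flips sign at a
configurable time (default 24 months), simulated piecewise by inversion —
used only to verify the PH diagnostic has power.

## Survival statistics

Tertiles are assigned by rank: sorted ascending with ties broken by
patient id, the first ⌈n/3⌉ ranks are the lower and the last ⌈n/3⌉ the
upper tertile. At n = 86 this gives the 29/28/29 split; the rule is
documented because published tertile sizes are not always reconstructible
when scores tie at zero. Cox models are fitted by `survival::coxph` with
Efron tie handling by default — Breslow (the SPSS default, hence likely
the original software's choice) is available and the choice is recorded
in every fit object. Reference levels are the first (clinically
unexposed) category. Continuous covariates enter per unit.

Backward elimination removes, at each step, the variable with the largest
Wald p-value at or above the removal threshold, refitting until all
survivors are below it. The threshold defaults to 0.10, not 0.05: a
published backward-eliminated model that retains a factor at p = 0.078
while dropping others is inconsistent with a 0.05 removal rule, and 0.10
is a common choice that reproduces that behavior. Factors use a
multi-degree-of-freedom Wald test.

The PH diagnostic correlates each variable's scaled Schoenfeld residuals
with the (untransformed) event times and tests the Pearson correlation
with a t-test — the "partial residuals against time" check in its
simplest form. `survival::cox.zph` (identity transform) is used in the
test suite as an independent cross-check, never as the implementation.
Calibration is verified by simulation: the type-I error at α = 0.05 sits
inside 0.05 ± 0.04 over 200 proportional-hazards replicates, and power
against the sign-flip violation at n = 1000 exceeds 0.9.

Survival curves come in both flavors emitted by the original analysis:
Cox-based curves (Breslow baseline cumulative hazard raised to
exp(β_g) per tertile) and Kaplan–Meier curves, with the k-group log-rank
test. Two identical groups give a log-rank χ² of exactly zero.

## Numerical and degenerate-input choices

* Quantization: rendering uses `I = round(256·10^−OD − 1)`, the exact
  inverse of the OD transform; unmixing a noise-free render recovers the
  drawn ODs to within the half-level quantization bound.
* Otsu on a constant map, an empty ROI, shape mismatches, unknown
  exclusion-reason codes, fewer than 3 tertile values, no events, and
  fewer than 3 events for the PH test are all hard errors with
  instructive messages.
* A two-observation cohort with one event per group has a *monotone*
  partial likelihood (no finite maximizer); the fit is flagged
  non-converged rather than returning a misleading number.
* Batch scoring isolates failures per sample and continues, since slide
  batches routinely contain unreadable files; an all-failed batch aborts.
* All generator randomness flows from a single integer seed; identical
  seed and configuration give bit-identical images and cohorts.
  Registration and scoring contain no randomness at all.

## Problem sizes used in the packaged analyses

The packaged analyses and checks use 160×160 px tiles (20-pair scoring
benchmark, 50-trial registration sweep), n = 2000 cohorts for parameter
recovery, 200 replicates at n = 150 for PH calibration and 20 at
n = 1000 for PH power, and n = 500 for confidence-interval coverage.
These sizes were chosen so each statistic is estimated with useful
precision while a full run of the suite stays comfortably interactive;
all of them are parameters, not constants.

## Known limitations

* The stain vectors for NBT/BCIP and nuclear fast red are package
  defaults, not measured values; on real material they should be
  calibrated per scanner and batch.
* Registration is global and affine; strongly folded or torn sections
  violate its model.
* The synthetic benchmark shares texture between sections (see above),
  so it bounds algorithmic error, not biological section-to-section
  variation.
* The survival workflow models disease-free survival only; competing
  risks and covariate imputation are out of scope.
* The score's physical meaning (integrated chromogen OD) holds only as
  far as Beer–Lambert linearity does; very dense precipitate saturates.
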