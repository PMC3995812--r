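# mirstroma

Compartment-specific quantification of chromogenic in situ hybridization
(ISH) signal in tumor tissue, with the downstream survival analysis. The
package is for researchers who measure a transcript's expression
*specifically in the tumor stroma* — here motivated by microRNA-21, which
concentrates in the activated-fibroblast stroma of oral squamous cell
carcinomas and carries prognostic information there that the same signal
in the tumor epithelium does not.

## The measurement

A single ISH section cannot tell stromal from epithelial signal. The
package implements *virtual double staining* over serial sections:

1. a pan-cytokeratin IHC section (brown DAB) is unmixed into
   optical-density (OD) stain maps and thresholded to a tumor-epithelium
   mask;
2. the IHC section is registered onto the ISH section (normalized
   cross-correlation of total-OD maps, deterministic coarse-to-fine
   search over translation + rotation + isotropic scale);
3. the tumor mask and region of interest (ROI) are warped across;
4. the ISH section (blue NBT/BCIP chromogen, nuclear fast red
   counterstain) is unmixed and thresholded (Otsu by default), and within
   the ROI the scores are computed:

   - TBS — total blue signal in stroma: `A_blue,stroma × mean OD_blue`,
     i.e. the integrated blue-chromogen OD over positive stromal pixels;
   - TBT — the same in the tumor compartment;
   - TSA — total stroma area (ROI pixels not occupied by tumor cells).

Patients are then split into TBS tertiles and analyzed by Cox
proportional-hazards regression of disease-free survival: Spearman
screening, univariate models per clinical factor, a multivariate model
with backward elimination (removal threshold 0.10, Wald), Schoenfeld
residual PH diagnostics, and Cox / Kaplan–Meier tertile curves.

A synthetic-data generator produces paired section images with exact
per-pixel ground truth and survival cohorts with configured hazard
ratios, so every stage is testable without access to slides or patient
records.

## Worked example

```r
library(mirstroma)

pair <- simulate_image_pair(image_sim_config(seed = 1))
res  <- score_sample(pair$ihc_image, pair$ish_image, roi = pair$roi_mask)
res$scores
#> <score_panel>
#>   TBS 2009.63 (area 4639 x mean OD 0.4332)
#>   TBT 103.90 (area 256 x mean OD 0.4058)
#>   TSA 13342 px (negative stroma 8703 px)
pair$tbs_true
#> [1] 2087.799
```

The measured TBS is within 4% of the generator's ground truth (the
truth is the exact sum of the drawn blue ODs over positive stromal
pixels). On the cohort side:

```r
co <- simulate_cohort(cohort_sim_config(n_patients = 2000,
                                        preset = "multivariate", seed = 1))
b  <- run_survival(NULL, co)
b$multivariate$fit
#> <cox_fit> n=2000 events=665 ties=efron
#>                  HR         CI95        p
#> n_statusN+    2.444 (2.08, 2.87) 2.41e-27
#> perineuralyes 2.322 (1.95, 2.77) 8.75e-21
#> score_tertile 1.523 (1.38, 1.68) 8.85e-18
```

The generator's conditional hazard ratios are 2.5 (nodal status), 2.1
(perineural invasion) and 1.6 per stromal-tertile step; stage — which is
TNM-derived and marginally prognostic but conditionally null — enters
the candidate set and is eliminated (p = 0.22), exactly the behavior
backward elimination should show.

The numbered scripts under `analysis/` run the full workflow
(simulate images → score → simulate cohorts → survival reports) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_images.R
Rscript analysis/02_score_images.R
Rscript analysis/03_simulate_cohort.R
Rscript analysis/04_survival_analysis.R
```

A deterministic 86-patient example clinical table with published-style
margins (63/23 gender, 21 node-positive, 68 surgery-only, 10 patients
with zero stromal score, ...) is available as `example_clinical_table()`,
and `example_selection_manifest()` carries the 111-case selection
manifest whose exclusions (10 misclassified, 9 insufficient material,
6 poor technical quality) leave the 86-patient cohort.

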