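# gasegr

Multimodal deep-learning segmentation of geographic atrophy (GA) on paired
fundus autofluorescence (FAF) and near-infrared reflectance (NIR) images,
with the complete cross-sectional and longitudinal agreement pipeline used
to judge automated GA grading against human experts — plus a synthetic
fundus phantom generator that makes the whole pipeline exercisable end to
end without clinical data.

## Who this is for

Researchers building or validating automated GA lesion grading: GA appears
on FAF as sharply demarcated hypoautofluorescent regions, change in total
lesion area (mm²) is an accepted clinical-trial endpoint, and NIR is the
supportive modality that disambiguates the fovea, which is dark on FAF and
easily mistaken for atrophy.

## What is inside

* **Networks** — encoder–decoder segmentation models built on
  `RcppArmadillo` with hand-derived backpropagation:
  * UNet: `Z,S = E(concat(FAF, NIR)); P = D(Z, S)` — one encoder on the
    channel-stacked pair;
  * YNet: `Z1,S1 = E1(FAF); Z2,S2 = E2(NIR); P = D(concat(Z1,Z2), S1)` —
    two modality-specific encoders, joint decoder, and *FAF-only* skip
    residuals (the NIR branch acts through its bottleneck embedding only).
* **Edge-reweighted Dice loss** — training targets weight lesion borders
  (1.0) above interiors (decaying to ≥ 0.5) and the loss is 1 minus a
  weight-inserted soft Dice
  `2·Σ v·p·g / (Σ v·p + Σ v·g)` with unit background weight; validation
  always scores plain Dice on the original masks at a strict 0.5
  threshold.
* **Training recipe** — Adam, batch size 4, lr 1e-3 ×0.1 every 30 epochs,
  100 epochs, no early stopping; patient-level train/validation splits
  enforced.
* **Mask analytics** — connected-component lesion spots with the 0.05 mm²
  minimal-size rule, focality, total area in mm².
* **Agreement statistics** — per-visit and pooled Dice tables for every
  grader/network pair, Pearson r and Passing–Bablok regression against the
  average grader, generalized multi-rater Bland–Altman with grader-derived
  95% limits, per-interval enlargement with SE and coefficient of
  variation, and subgroup analyses (baseline area, focality, foveal
  involvement).
* **Synthetic cohorts** — registered FAF/NIR phantom pairs with ground
  truth, two simulated graders (default noise calibrated to an
  intergrader Dice of ≈ 0.94), vessel/opacity artifacts, an FAF-only
  foveal confound, and programmable lesion growth.

## Worked example

```r
library(gasegr)

# 1. simulate a small longitudinal cohort (writes PNGs + manifest.csv)
mf <- generate_cohort(12, visits = c("SCR", "M6"), out_dir = "cohort",
                      seed = 1, image_size = 128)
recs <- load_manifest(mf)

# 2. patient-level split and desk-scale training
sp <- patient_split(mf, c(train = 0.75, val = 0.25), seed = 1)
tr <- recs[sapply(recs, function(r) r$patient_id %in% sp$train$patient_id)]
va <- recs[sapply(recs, function(r) r$patient_id %in% sp$val$patient_id)]
fit <- train_segnet(build_model(model_config("ynet", 64, depth = 3,
                                             base_channels = 8, seed = 1)),
                    tr, va, train_config(epochs = 15, seed = 1))
print(fit)

# 3. predict and run the agreement pipeline
masks <- list(YNet = lapply(recs, function(r)
  binarize(predict(fit, r), 0.5, r$scale_mm_per_px)))
report <- evaluate_cohort(recs, masks, intervals = list(c("SCR", "M6")))
print(report)
```

Output from this exact script (seed 1):

```
<segnet> YNET, input 64x64, depth 3, base channels 8, trained
  parameters: 49,409
  epochs: 15, final train loss 0.0752, final val Dice 0.9426
Agreement report
  comparison pairs: grader1-YNet, grader2-YNet, grader1-grader2
  Dice (mean [SD]):
    All  n= 24  grader1-YNet 0.929 (0.032)  grader2-YNet 0.929 (0.038)  grader1-grader2 0.964 (0.022)
    SCR  n= 12  grader1-YNet 0.927 (0.035)  grader2-YNet 0.926 (0.044)  grader1-grader2 0.963 (0.023)
    M6   n= 12  grader1-YNet 0.932 (0.030)  grader2-YNet 0.932 (0.031)  grader1-grader2 0.965 (0.021)
  cross-sectional area agreement at SCR:
    YNet vs avg_grader       r = 0.999 (n = 12), PB slope 0.995 intercept 0.591
    grader1 vs grader2       r = 0.999 (n = 12), PB slope 0.975 intercept 0.204
  enlargement SCR->M6: avg_grader 0.93+/-0.05  grader1 0.92+/-0.08  grader2 0.94+/-0.08  truth 1.00+/-0.01  YNet 0.98+/-0.04
```

Reading it: after fifteen desk-scale epochs on nine training patients the
YNet agrees with each simulated grader at a mean Dice of 0.93 while the two
graders agree at 0.96 (their noise-calibrated ceiling at this raster
scale); lesion areas track the average grader at r = 0.999 with a
Passing-Bablok slope of 0.995; and the recovered cohort mean enlargement
(YNet 0.98 +/- 0.04 mm2 per 6 months; graders 0.92-0.94) brackets the
programmed growth of 1.0 mm2, which the ground truth pins at 1.00 +/- 0.01.

A command-line surface wrapping the same functions ships in
`inst/cli/gasegr`:

```sh
Rscript inst/cli/gasegr simulate --out cohort --n-patients 10 --seed 1
Rscript inst/cli/gasegr train --manifest cohort/manifest.csv --arch ynet --out run
Rscript inst/cli/gasegr predict --manifest cohort/manifest.csv --model run/ynet_model.rds --out preds
Rscript inst/cli/gasegr evaluate --manifest cohort/manifest.csv --predictions YNet=preds --out report
```

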