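---
title: "Methods: multimodal GA segmentation and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal GA segmentation and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Geographic atrophy (GA) is the atrophic late stage of age-related macular
degeneration. On fundus autofluorescence (FAF) imaging, GA lesions appear as
sharply demarcated hypoautofluorescent (dark) regions, and change in total
lesion area over time is an accepted anatomical endpoint in clinical trials.
Near-infrared reflectance (NIR), acquired on the same device, is a
supportive modality: it is less affected by media opacities and by the
macular pigment that darkens the fovea on FAF, so structures that are
ambiguous on FAF (most prominently the fovea itself) are often cleanly
separable on NIR.

`gasegr` implements an automated GA segmentation pipeline on registered
FAF/NIR pairs, together with the statistical machinery needed to judge such
a pipeline the way reading centers do: Dice overlap against expert graders,
cross-sectional area agreement (Pearson correlation, Passing–Bablok
regression, multi-rater Bland–Altman limits), and longitudinal enlargement
with its coefficient of variation. Because clinical image sets of this kind
are not redistributable, the package also ships a synthetic fundus phantom
generator that reproduces the salient structure of such data and serves as
the fixture source for every test in the package.

## Segmentation networks

Two encoder–decoder families are provided, built from scratch on
`RcppArmadillo` primitives (3×3 same-padded convolutions via im2col/GEMM,
2×2 max-pooling, 2×2-stride-2 transposed convolutions, ReLU activations,
terminal sigmoid), with hand-derived backpropagation verified against
central finite differences (relative error below 5×10⁻⁵):

* **UNet** — one encoder over the channel-stacked pair:
  `Z, S = E(concat(FAF, NIR)); P = D(Z, S)`.
* **YNet** — two modality-specific encoders and a joint decoder:
  `Z1, S1 = E1(FAF); Z2, S2 = E2(NIR); P = D(concat(Z1, Z2), S1)`.
  The two encoders are architecturally identical to the UNet encoder except
  that each takes a single-channel image; the decoder matches the UNet
  decoder except that its bottleneck input has twice as many channels.
  Only the FAF encoder's skip residuals reach the decoder: the NIR branch
  influences the output exclusively through its bottleneck embedding. This
  is a testable contract (`decoder_skips()` is invariant to any NIR
  perturbation) and is the architectural reason to expect the YNet to be
  better at ignoring FAF-only confounds such as the dark fovea.

The precise block design inside each stage is not prescribed by the
architecture equations above; we use the standard double-convolution block
(two 3×3 convolutions with ReLU) per resolution stage, max-pool
downsampling, transposed-convolution upsampling, and channel width doubling
per stage from `base_channels`. A network of `depth` d has d−1 skip
connections and an input size divisible by 2^d. Inputs are *not* intensity
normalized; images are resized bilinearly, masks by nearest neighbour.

Weight initialization is He-scaled Gaussian drawn deterministically from
the configuration seed, so builds and training runs are bit-reproducible.

## Edge-reweighted Dice loss

Training targets are modified ground-truth masks that emphasize lesion
borders: background pixels get weight 0, lesion pixels within
`edge_band_px` of the boundary get weight 1, and deeper interior pixels
decay linearly with Chebyshev distance to the background down to
`interior_floor` (default 0.5), per connected component. The rationale is
that lesion interiors are easy (uniformly dark) while the clinically
meaningful information is in the boundary placement.

The loss is 1 minus a weight-inserted soft Dice,

$$D_w(p) = \frac{2\sum_i v_i\,p_i\,g_i}{\sum_i v_i p_i + \sum_i v_i g_i},
\qquad v_i = \begin{cases} w_i & g_i = 1\\ 1 & g_i = 0,\end{cases}$$

where `g` is the binary mask, `w` the reweighted mask and `p` the predicted
probabilities. The design constraints were: a perfect prediction must score
1 for any weight map; with all lesion weights at 1 the statistic must reduce
*exactly* to the ordinary soft Dice; border errors must cost more than
interior errors; and background false positives must remain penalized
(hence the unit background weight — a weight of 0 outside the lesion would
make false positives free and the loss degenerate). The analytic gradient
used by the optimizer is checked against finite differences in the test
suite.

Validation and testing never see the reweighted masks: per epoch, the
probability maps are binarized with a strict 0.5 threshold and scored by
ordinary Dice against the original binary masks.

## Training recipe

Adam, batch size 4, initial learning rate 10⁻³ multiplied by 0.1 every 30
epochs, 100 epochs, no early stopping, no data augmentation; the loss is
computed per image and averaged over the batch. Final-epoch weights are the
trained model (a best-validation checkpoint is available behind a flag, off
by default). Training/validation cohorts must be disjoint at the patient
level; an overlap is a hard error. The full-scale profile is 768×768
inputs, depth 4, 32 base channels; the desk-scale profile used throughout
the tests and the acceptance script is 64×64, depth 3, 8 base channels, 30
epochs, which trains in a few minutes on one CPU core and reaches held-out
Dice above 0.95 on default phantoms.

## Mask analytics

Lesion *spots* are connected components (8-connected by default,
4-connected selectable). Spots smaller than 0.05 mm² — roughly a 175 µm
equivalent diameter, the conventional minimal size for a countable GA
lesion — are disregarded; focality is the number of surviving spots and
total area their sum. The filter is always applied when measuring areas;
applying it to network predictions before Dice is optional
(`filter_predictions`) and off by default, since the minimal-size rule is a
grading convention rather than a property of the segmentation. Pixel scale
defaults to an 8.85 mm 30° field divided by the raster width and is
configuration, not hard-coded truth: real acquisitions carry their scale
through the manifest.

## Agreement statistics

* **Dice tables** per comparison pair (each network against each grader,
  grader against grader), per visit and pooled. Pooling is per image across
  visits (the per-visit means are recoverable from the table; the pooled
  row equals the image-count-weighted combination).
* **Cross-sectional area agreement** at a reference visit: Pearson r and
  Passing–Bablok regression of each network against the *average grader*
  (the per-image mean of grader areas — areas are averaged, not masks),
  plus the grader–grader benchmark. The Passing–Bablok slope is the
  shifted median of pairwise slopes with the classical handling of ties and
  negative reciprocals (slopes of exactly −1 discarded, median index offset
  by the count of slopes below −1) and rank-based confidence bounds.
* **Generalized Bland–Altman**: per patient-visit, the reference value is
  the mean grader area and each source's difference is taken from it; the
  95% limits of agreement (mean ± 1.96·SD, sample SD throughout the
  package) are computed over the *grader* differences only, and network
  sources are judged against those grader-derived limits.
* **Enlargement**: absolute change in area (mm²) between two visits, per
  patient and source, with cohort mean and standard error, an optional
  complete-case restriction, and the coefficient of variation SD/mean.
  An optional outlier rule (|δ − median| > 5·MAD, off by default) is
  provided for longitudinal correlations; the underlying convention in the
  source literature is not fully specified, so the rule is explicit and
  optional rather than silently applied.
* **Subgroup analysis** by baseline lesion area (median split and
  continuous correlation), focality (unifocal vs multifocal) and foveal
  involvement (truth lesion intersecting a configurable central disc,
  default radius 0.25 mm); subgroups under 3 images report `NA`.

## The synthetic phantom generator

`phantom_spec()`/`generate_phantom()` emulate the structure the pipeline
must cope with, not the optics of a cSLO:

* lesions are unions of foci with smooth random-harmonic boundaries
  (orders 2–5, amplitude `lesion_boundary_roughness`), rendered dark on a
  bright FAF background and at deliberately low contrast on NIR. The
  harmonic boundary is normalized so the enclosed area equals πr² exactly
  for every draw, keeping programmed areas and growth rates unbiased;
* the **fovea** is a dark patch on FAF only (NIR is clean there), the key
  modality-specific confound. The truth mask never includes the foveal
  disc: phantoms follow the fovea-sparing phenotype, and a focus large
  enough to contain the disc is placed centrally with its radius inflated
  to compensate the carved-out foveal area. This also resolves a geometric
  impossibility: an eccentric fovea-avoiding circular lesion at the upper
  end of the eligibility range (17.78 mm² plus growth margin) cannot fit
  an 8.85 mm field;
* thin dark vessel arcs cross both channels and an occasional opacity
  streak darkens FAF only;
* longitudinal growth scales all focus radii so total area increases by
  `growth_rate_mm2_per_6mo` per visit step (default 1.0 mm²/6 months, a
  typical GA progression rate); visits are pre-registered (fixed centers),
  and satellite foci are kept disjoint at full growth;
* cohort sampling draws baseline total area uniformly inside the
  eligibility window 2.54–17.78 mm²; multifocal phantoms (40% by default)
  receive small satellite foci (0.15–0.8 mm²) with the dominant focus
  carrying the remainder, at least 1.27 mm².

Simulated graders perturb the truth boundary by thresholding the signed
quasi-Euclidean boundary distance at a low-frequency Gaussian field
(16-pixel grid, bilinearly upsampled), giving spatially coherent over- and
under-segmentation strokes; zero noise returns the truth exactly. The
default noise SD of 2.7 px was calibrated once by simulation so that two
independent graders agree at a mean Dice of ≈0.94 on default phantoms,
matching the intergrader agreement reading centers typically report.

What the phantoms deliberately do **not** model: real FAF texture and
speckle, media-opacity-induced global quality loss, registration error
between visits, non-GA pathology, and lesion regression. Passing the
package's synthetic recovery tests therefore demonstrates that the
implementation is correct and the pipeline is sensitive at realistic
geometry and noise scales — not that the networks would reach the same
accuracy on clinical images.

## Numerical choices and edge cases

* Dice of two empty masks is defined as 1 (agreement), empty vs non-empty
  as 0 — needed for lesion-free controls.
* Binarization uses the strict inequality `p > 0.5`: a map exactly at the
  threshold stays background.
* All SDs are sample (n−1) SDs; CV is undefined (an error) at zero mean;
  Pearson correlation on constant input is an explicit error, not `NA`.
* Chebyshev distance (two-pass chamfer) defines the reweighting profile;
  a (3,4)/3 chamfer approximates the Euclidean metric for the grader
  displacement field. An all-lesion raster falls back to the raster border
  as the boundary.
* Learning rate at epoch e (0-based) is `lr0 · factor^⌊e/step⌋`; with the
  default recipe this is 10⁻³/10⁻⁴/10⁻⁵ over epochs 0–29/30–59/60–89 and
  continues to decay every 30 epochs thereafter.
* Records lacking an NIR image are excluded with a named reason rather
  than failing the whole manifest, mirroring how FAF-only acquisitions are
  handled in practice; any other manifest defect is a per-row error.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the complete suite executes on a single CPU core in well under
half an hour: 64×64 phantoms (depth 3, 8 base channels, 30 epochs, 60
patients) for segmentation recovery, 30 patients × 24 epochs × 3 seeds for
the fovea-confound comparison, 40 patients at 128×128 for longitudinal
recovery, and 50 phantoms at 256×256 for grader calibration. The full-scale
768×768/depth-4/100-epoch profile is available through the same
configuration objects.
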