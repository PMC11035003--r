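---
title: "Methods: ADC-map texture analysis for chemotherapy response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADC-map texture analysis for chemotherapy response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Locally advanced rectal cancer (LARC) is commonly treated with neoadjuvant
chemotherapy (NCT) before total mesorectal excision. A substantial minority
of patients — roughly a fifth at typical centers — do not respond
(pathological tumor regression grade pTRG 3), and identifying them *before*
surgery would let clinicians consider additional radiation. Diffusion-weighted
MRI offers a quantitative window: the apparent diffusion coefficient (ADC,
units 10^-3 mm^2/s) falls with cellularity, and effective treatment usually
raises tumor ADC. `adctex` implements a complete analysis pipeline for this
question: first-order texture features on pre- and post-treatment ADC maps,
inter-reader reproducibility filtering, a random-forest texture (TA)
classifier, a stepwise-logistic manual-ADC model, simulated subjective
readings, and a ROC/DeLong/kappa comparison stack — together with a synthetic
cohort generator so every stage is testable without patient data.

## Feature definitions and conventions

For the masked ROI pixel sample at one timepoint the package computes mean,
standard deviation, variance, skewness, excess kurtosis and histogram
entropy; each feature also exists as a pre-to-post `*_change` (always
post − pre). Three conventions deserve emphasis, because the field's
reporting is not uniform:

* **Entropy sign.** Entropy is `sum(p * log2(p))` over a 256-bin histogram
  of ROI values min–max scaled to [0, 255] — the *negative* of Shannon
  entropy, bounded in [−8, 0]. This matches how ADC texture tables in the
  clinical literature print entropies near −5; a nonnegative Shannon
  convention cannot produce those values.
* **Kurtosis.** Excess kurtosis (`m4/m2^2 − 3`), so a Gaussian ROI scores 0.
  Reported post-treatment kurtoses below 1 are impossible under the
  non-excess convention, whose floor is 1.
* **Units.** ROI means are reported on the native 10^-3 mm^2/s pixel scale;
  the SD is reported in 10^-5 mm^2/s (raw SD × 100) and the variance as the
  square of the *reported* SD. This reconciles published tables in which
  means sit near 1, SDs near 12 and variances near 150 with
  variance ≈ SD².

Population (biased) central moments are used for skewness and kurtosis —
the default in image-texture toolchains, and the sample-size correction is
negligible at ROI sizes of order 10^3 pixels. A constant ROI is flagged
degenerate: SD, variance and entropy are 0 and the shape statistics are
returned as 0 rather than 0/0. Histogram bins are left-closed/right-open
with the maximum value assigned to the last bin; a zero-width intensity
range occupies one bin and has entropy 0. The per-ROI min–max gray-level
mapping doubles as the normalization step, which makes all shape features
(and entropy) invariant to global intensity scaling — this is exactly what
lets the pipeline absorb a between-scanner intensity shift in the external
cohort. A whole-image z-score alternative would not share that exact
invariance and was not adopted.

Manual ADC values (`pre_ADC`, `post_ADC`, `ADC_change`) are the average of
two readers' ROI means; there is deliberately no single-reader fallback —
a missing reader is an error, because the averaged measurement is the
defined quantity.

## The synthetic cohort generator

No imaging data are distributed with this problem, so the generator is a
first-class module: it must realize group-level summary statistics as pixel
data whose *extracted* features have those statistics.

**Disaggregation.** Published tables give only group means ± SDs for each
feature. Per-patient targets are drawn from a multivariate normal over
eight primitives (pre level and pre-to-post change of mean, SD, skewness,
kurtosis) with exchangeable correlation ρ = 0.3. The correlation value is
an explicit assumption, not a published fact: histogram statistics of the
same ROI are mildly positively dependent, and independence would understate
the separation a multivariate classifier can achieve. Post-treatment
targets are pre + change by construction, so change features carry the
configured change statistics exactly; post-level dispersions are emergent
(e.g. the post-mean SD is `sqrt(sd_pre² + sd_change² + 2ρ·sd_pre·sd_change)`
rather than the table's printed post SD — matching both simultaneously is
overdetermined, and the change rows are the quantities the models use).

**Feasibility.** A skewness/kurtosis pair must satisfy
`kurt ≥ 1.641·skew² − 1.226` (plus a 0.1 safety margin) to be realizable by
the cubic transform below. Published kurtosis dispersions (± ~3) put an
appreciable fraction of Gaussian draws below that floor; infeasible pairs
are projected to the nearest boundary point (Euclidean, in the unitless
skew/kurt plane). Consequence worth stating plainly: group means of
*skewness and kurtosis* targets are biased toward the feasible region,
while mean and SD targets recover their configured group statistics
exactly in expectation. Passing the group-recovery checks therefore
demonstrates calibration of the location/scale features, not of the shape
features, whose printed dispersions are mutually inconsistent with moment
feasibility.

**Pixel realization.** ROI pixels are a cubic polynomial transform
`y = z + c·z² + d·z³` of i.i.d. standard normal noise. Rather than solving
the classical population equations, the coefficients are optimized against
the *empirical* moments of the actual noise draw, and the mean/SD are then
fixed exactly by an affine step (skewness and kurtosis are
affine-invariant). This makes the realized sample match its mean and SD to
machine precision and its shape moments to the solver tolerance (~10^-3),
well inside the package's stated tolerances (1% relative on mean/SD, 0.1
absolute on skewness/kurtosis). Pixels are spatially i.i.d.: every feature
in scope is histogram-based and blind to spatial arrangement, so simulating
spatial texture would add nothing the features can see. Positivity (ADC of
tissue is strictly positive) is enforced by rejecting noise draws that
cross zero; for heavy-tailed targets where every draw crosses zero, the
left tail is clipped at a small epsilon and the exact mean/SD restored,
with the clipped pixel count logged per image. A global additive shift was
rejected: it silently biases the realized mean and, at cohort level,
measurably distorted change features.

**ROI geometry and the second reader.** Each patient gets an elliptical
consensus ROI (radii 26–36% and 22–32% of the 64×64 image, jittered
center). The second reader's mask perturbs radii and center by a
configurable fraction (default 0.05, chosen once as representative of
experienced readers re-outlining the same tumor). A band of tumor-like,
moment-matched intensities (1.25× radii) surrounds the ROI so that a
plausibly misplaced boundary samples partial-volume tumor edge rather than
clean background; without it, a few misplaced boundary pixels drag in
background at ~1.4×10^-3 mm^2/s and collapse the ICC of shape features far
below anything observed with real readers. Entropy is not independently
targeted — it is an emergent property of the realized histogram.

**Subjective readers.** Binary mrTRG-style calls are Bernoulli at a
configured sensitivity/specificity per reader (defaults 27.8%/95.6% and
30.6%/94.9%), independent across patients.

## Models

**TA model.** A random forest (500 trees, unrestricted depth, √p candidate
features per split, no class weighting — all configurable) on features that
survive the reproducibility filter; feature selection takes the top k = 5
by Gini (mean-decrease-in-impurity) importance, ties broken by name so the
ranking is deterministic given the seed. The predicted score is the
fraction of trees voting nonresponse. Resubstitution performance of such a
forest is near-perfect by construction; the pipeline therefore labels
resubstitution and validation performance explicitly and never mixes them.

**ADC model.** Candidates are the manual ADC quantities whose two-group
comparison is significant at 0.05; forward likelihood-ratio stepwise
logistic regression (enter < 0.05, remove > 0.10, the common
statistical-package defaults) builds the model. Stepwise selection over
correlated candidates can cycle; a visited-model-signature guard terminates
the loop. Quasi-complete separation falls back to a lightly
ridge-penalized fit for the reported coefficients (selection itself is
driven by the unpenalized deviances, which remain finite), with a warning.
When no candidate is significant the model is intercept-only: a constant
risk score with AUC 0.5.

## Evaluation stack

ROC curves are computed over all score thresholds; the trapezoidal AUC
equals the Mann–Whitney statistic U/(n₁n₂) with ties counted ½ (asserted
exactly in tests). AUC variance uses DeLong structural components with a
Wald 95% CI clipped to [0, 1] (the exact CI method behind published
MedCalc-style tables is unstated; Wald-with-DeLong-SE is the conventional
choice). The reported operating point maximizes the Youden index, ties
broken toward higher specificity. A binary rater enters the same machinery
as a two-point ROC, giving AUC = (sensitivity + specificity)/2. Paired
AUCs are compared with the DeLong test; when the estimated variance of the
difference is zero, the statistic follows reference implementations —
equal AUCs give p = 1, while unequal AUCs (a perfect separator against a
constant score, which occurs whenever the ADC screening admits no
candidate) give a divergent z with p reported as 0. Agreement between readers is Cohen's kappa with the
Fleiss–Cohen–Everitt large-sample standard error. Two-group comparisons
follow the clinical-table rule: Shapiro–Wilk at α = 0.05 per group selects
Student's t (pooled; Welch by option) or Mann–Whitney U; categorical
tables use χ² without continuity correction when n ≥ 40 and all expected
counts are ≥ 5, otherwise Fisher's exact test.

## Pipeline and cohorts

`run_pipeline()` generates a single-center pool (default 45 + 198),
splits it 0.8/0.2 into primary and internal-validation cohorts (simple
random split by default; a stratified option exists because stratification
is a reasonable alternative reading), and generates an external cohort
(default 33 + 23, the reversed prevalence of a referral center) whose
images carry a global ±10% intensity scale to emulate different equipment
— exercising the per-ROI normalization. Feature selection and model
fitting see only primary-cohort labels; tests assert that predictions are
unchanged when validation labels are permuted.

## Problem sizes and determinism

The test suite exercises study-scale cohorts (36 + 158 primary) for the
model-comparison checks, 20 independent seeds for the superiority
property, 1,000 random feasible targets for moment recovery, 200,000
bootstrap draws for the DeLong oracle, and 2,000 replicates for the
type-I-error check — sizes chosen so each check has enough resolution at
its stated tolerance while the whole suite stays comfortably runnable on a
laptop. Every stochastic element derives from an explicit integer seed;
identical (config, seed) reproduces manifests, images, fits and report
JSON byte-for-byte.

## What passing tests do and do not show

The generator realizes histogram statistics, not rectal anatomy: no
lumen/necrosis exclusions, no spatial texture, no scanner physics, no 3D
volumes. Group separations are Gaussian in the targets, so simulated
model performance does not predict performance on real ADC maps; in
particular, validation AUCs on synthetic cohorts reflect the configured
effect sizes and correlation assumption, not any property of real tumors.
What the suite does establish: the feature extractor, reproducibility
filter, selection procedures, models and every statistical engine compute
what they claim, at stated tolerances, against independent oracles.

## Known limitations

* Manual ADC in simulation tracks the ROI mean, so the simulated
  `ADC_change` separation inherits the mean-change effect size; published
  Mann–Whitney p-values for skewed real-data features cannot be reproduced
  from means ± SDs alone.
* The ICC uses ICC(2,1) absolute agreement (single measurement); whether
  published tables used single- or average-measure ICC is typically
  unstated. A consistency variant is available.
* Whether feature selection in published pipelines was cross-validated is
  usually unstated; the default here selects on the primary cohort only,
  and reports resubstitution and out-of-fold performance separately.
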