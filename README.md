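# adctex

Texture analysis of apparent diffusion coefficient (ADC) maps for
identifying non-responders to neoadjuvant chemotherapy (NCT) in locally
advanced rectal cancer.

Roughly one in five rectal-cancer patients gains nothing from neoadjuvant
chemotherapy (pathological tumor regression grade pTRG 3). Spotting them
before surgery — when additional radiation is still an option — is a
quantitative-imaging problem: treatment response changes both the level and
the shape of the tumor's ADC histogram. `adctex` is aimed at imaging
researchers who want a fully tested, reproducible implementation of the
standard first-order-texture workflow for this question, including a
synthetic cohort generator so the whole pipeline runs and is verifiable
without any patient data.

## What it computes

For each patient with pre- and post-treatment ADC maps and ROI masks:

* **First-order texture features** of the masked histogram at both
  timepoints and their changes (change = post − pre): mean
  (10⁻³ mm²/s), SD (reported in 10⁻⁵ mm²/s), variance (= reported SD²),
  skewness m₃/m₂^1.5, excess kurtosis m₄/m₂² − 3, and histogram entropy
  Σp·log₂p over 256 min–max-scaled bins (signed convention, in [−8, 0]).
* **Manual ADC values** — dual-reader averaged ROI means
  (`pre_ADC`, `post_ADC`, `ADC_change`).
* **Reproducibility filtering** — ICC(2,1), two-way random effects,
  absolute agreement, on dual-reader delineations; features kept when
  ICC > 0.75.
* **Models** — a random-forest TA classifier on the top-5 features by Gini
  importance, and a forward likelihood-ratio stepwise logistic model on the
  significant manual-ADC candidates.
* **Evaluation** — ROC with DeLong variance and Youden operating point
  (AUC ≡ Mann–Whitney U/(n₁n₂)), paired DeLong tests between models and
  binary raters (a binary rater's AUC is (sens + spec)/2), Cohen's kappa
  with Fleiss large-sample CI, and normality-adaptive two-group tests.

The synthetic generator turns group-level feature statistics (means ± SDs
for the two response classes) into per-patient targets via a correlated
Gaussian model, then realizes each target as ROI pixel data through a
cubic polynomial moment-matching transform — the extracted mean/SD match
their targets to machine precision and skewness/kurtosis to ~10⁻³.

## Worked example

```r
library(adctex)

# realize a target moment quadruple as an ADC image and recover it
r <- synthesize_roi_image(list(pre_mean = 0.906, pre_SD = 12.8,
                               pre_skewness = 0.405, pre_kurtosis = 1.133,
                               patient_id = "P001"),
                          "pre", seed = 42)
print(r$image)
#> <adc_map> P001/pre  64x64 px, spacing 1 mm, range [0.479, 1.574] x10^-3 mm^2/s
s <- first_order_stats(masked_pixels(r$image, r$mask))
cat(sprintf("mean %.4f | SD %.2f | skew %.3f | kurt %.3f | entropy %.3f\n",
            s$mean, s$sd, s$skewness, s$kurtosis, s$entropy))
#> mean 0.9060 | SD 12.80 | skew 0.405 | kurt 1.133 | entropy -6.860

# full study pipeline on synthetic cohorts
rep <- run_pipeline(seed = 1)
print(rep)
#> ADC texture-analysis pipeline report (seed 1 )
#>   primary:  TA AUC 1.000 | ADC AUC 0.631 | readers 0.638 / 0.595
#>   internal: TA AUC 0.679 | external: TA AUC 0.576
#>   DeLong TA vs ADC p = 9.34e-18; reader kappa = 0.124
#>   TA features: mean_change, pre_kurtosis, skewness_change, kurtosis_change, post_kurtosis
```

The first block shows the generator's contract: the four targeted moments
of the masked pixels equal their targets (mean and SD exactly, shape
moments within 10⁻³). The pipeline report gives resubstitution AUC of the
texture model on the primary cohort (near 1 by construction for a
500-tree forest — validation rows are the honest numbers), the
manual-ADC logistic model's AUC, the two simulated subjective readers,
the paired DeLong comparison and the inter-reader kappa. Selected
features vary by seed because the synthetic group differences are spread
over correlated features.

A thin CLI wrapper ships in `inst/cli/adct.R`:

```sh
Rscript inst/cli/adct.R simulate --out cohort_dir --seed 7
Rscript inst/cli/adct.R run --out report_dir --seed 7
```

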