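# dmnsubnet

Resting-state functional-connectivity analysis of default-mode-network
(DMN) subnetworks, for researchers studying intrinsic brain networks in
early psychosis (and anyone who needs a tested, reproducible pipeline
from node time series to symptom prediction). The package covers:

- **Motion quality control**: framewise displacement
  `FD_t = Σ|Δd_i| + r·Σ|Δθ_i|` (translations in mm, rotations converted
  on an `r = 50` mm sphere), spike ("scrubbing") regressors for frames
  with FD > 0.5 mm, exclusion when >17% of frames are flagged or absolute
  translation exceeds 3 mm, and nuisance regression (6 motion parameters,
  WM/CSF means, spike columns, DCT high-pass with
  `K = ⌊2·T·TR·f_c⌋` components).
- **Consensus parcellation**: signed weighted modularity
  `Q* = Q⁺ − v⁻/(v⁺+v⁻)·Q⁻` with resolution γ, maximized by a
  Louvain-type greedy optimizer run 1000 times; per-node stability from
  optimal cross-run community matching, nodes below 40% stability
  removed. Whole brain at γ = 1.25, DMN subclustering into posterior
  medial (PM), anterior temporal (AT) and medial prefrontal (MPF)
  subnetworks at γ = 1.00; agreement scored by normalized mutual
  information (mean-entropy normalization).
- **Connectivity statistics**: per-subject mean Fisher-z
  (`z = atanh r`) connectivity within and between the three subnetworks,
  pooled-variance two-sample t-tests (also from printed summary
  statistics), Pearson chi-square tests.
- **Symptom prediction**: bootstrapping-enhanced elastic net (α = 0.5,
  B = 5000): the variable inclusion probability (VIP) of a predictor is
  the fraction of bootstrap resamples in which its cross-validated
  penalized coefficient is nonzero; predictors with VIP > 70% are refit
  by OLS with dummy co-predictors and hierarchical R²-change F-tests.
- **A synthetic-cohort generator** with planted community structure and a
  planted symptom model, so every stage is testable against ground truth
  without access to clinical data.

Everything is tidyverse-shaped: tibbles in and out, `tidy()` / `glance()`
methods for fitted objects, `autoplot()` for VIP and stability plots.

## Worked example

Simulate a study-scale cohort (69 subjects; 28 patients with symptom
scores), run the full pipeline, and predict negative-symptom severity:

```r
library(dmnsubnet)

cfg    <- simulation_config(n_subjects = 69, seed = 42)
cohort <- generate_cohort(cfg)

pipe <- run_dmn_pipeline(cohort, iterations = 200, seed = 1,
                         dmn_mode = "union")
print(pipe$dmn)
#> DMN partition: 48 nodes, 3 communities
#>
#>  AT MPF  PM
#>  22   8  18

symptoms <- generate_symptoms(cfg, pipe$profiles, pipe$mean_fd)
subjects <- dplyr::rows_update(cohort$subjects, symptoms, by = "subject_id")
subjects$panss_negative[!subjects$has_symptoms] <- NA

fit <- predict_symptoms(pipe$profiles, subjects, pipe$mean_fd,
                        outcome = "panss_negative", B = 500, seed = 9)
print(fit$vip)
#> Bootstrap VIP (alpha = 0.5, B = 500, threshold = 0.70)
#>   mpf_at       0.992  *selected*
#>   mpf_pm       0.832  *selected*
#>   within_at    0.452
#>   within_pm    0.250
#>   mean_fd      0.230
#>   pm_at        0.226
#>   within_mpf   0.198
print(fit$model)
#> OLS refit: n = 28, R^2 = 0.677, adjusted R^2 = 0.651
#> mpf_pm mpf_at
#> -0.331 -0.751
```

The pipeline recovers the planted 18/22/8-node PM/AT/MPF structure, and
the bootstrapped elastic net selects exactly the two planted
between-subnetwork predictors (MPF–AT and MPF–PM), whose standardized OLS
betas carry the planted negative sign: lower medial-prefrontal
connectivity predicts more severe negative symptoms. The medication dummy
adds nothing (`fit$medication`: R² change 0.018, p = 0.25), as planted.

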