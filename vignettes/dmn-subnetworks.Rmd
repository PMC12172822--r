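---
title: "Default-mode subnetwork connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Default-mode subnetwork connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnsubnet)
```

# The analysis

`dmnsubnet` implements a resting-state functional-connectivity pipeline for
studying the subnetworks of the default-mode network (DMN) — posterior
medial (PM), anterior temporal (AT) and medial prefrontal (MPF) — and their
relation to clinical symptom severity in early psychosis. The pipeline has
four stages, each usable on its own:

1. **Motion QC and denoising** (`compute_fd()`, `flag_outliers()`,
   `exclusion_decision()`, `build_design()`, `regress_nuisance()`).
   Framewise displacement (FD) is the Power-type scalar: the sum of the six
   absolute realignment-parameter differentials between consecutive frames,
   with rotations converted to mm of arc on a 50 mm sphere. Frames with
   FD strictly above 0.5 mm receive one spike (scrubbing) regressor each;
   subjects are excluded when more than 17% of frames are flagged or when
   any translation strays more than 3 mm from the reference frame. Nuisance
   regression removes, per node, an intercept, the six realignment
   parameters, mean WM and CSF signals, the spike columns, and a discrete
   cosine high-pass basis with `K = floor(2 * T * TR * f_c)` components
   (7 for a 185-frame, TR = 2 s scan at the default 0.01 Hz cutoff).
2. **Parcellation** (`pearson_matrix()`, `group_average()`,
   `consensus_partition()`, `identify_dmn()`, `subcluster_dmn()`). Nodes
   are filtered by temporal signal-to-noise ratio (mean across subjects
   below 50 or any subject below 30, both strict, plus an "uncertain"
   reference-label rule). Community detection maximizes
   resolution-parametrized modularity on the signed weighted group-average
   correlation matrix, with the asymmetric positive/negative scheme (the
   negative part's contribution is down-weighted by its share of total
   weight). A Louvain-type greedy optimizer is run 1000 times with
   randomized sweep orders; the maximum-Q run serves as the reference
   partition, every run's communities are matched to it by optimal
   one-to-one maximal-overlap assignment, and each node's *stability* is
   the fraction of runs agreeing with its reference community. Nodes below
   0.40 stability are removed. The whole-brain level uses resolution
   gamma = 1.25 and the DMN level gamma = 1.00.
3. **Connectivity profiles and group statistics** (`fisher_z()`,
   `subnetwork_profile()`, `two_sample_t()`, `t_from_summary()`,
   `chi_square_counts()`). Each subject is summarized by six mean
   Fisher-z values — within PM / AT / MPF and between MPF-PM / PM-AT /
   MPF-AT — with the z-transform applied before averaging (the
   `r_first` mode averages r then transforms). Group comparisons use the
   pooled-variance Student t (df = n1 + n2 - 2), which is what reported
   degrees of freedom of the form t(67) with 30 + 39 subjects imply;
   chi-square tests are Pearson without continuity correction by default.
4. **Symptom prediction** (`bootstrap_vip()`, `ols_refit()`,
   `r2_change()`). The six profile measures plus mean FD enter a
   bootstrapping-enhanced elastic net (alpha = 0.5, B = 5000 resamples by
   default): each resample is refit with a cross-validated penalty, and a
   predictor's *variable inclusion probability* (VIP) is the fraction of
   resamples in which its coefficient is nonzero. Predictors with VIP
   strictly above 70% are refit by OLS (penalized estimates are biased),
   with medication or group dummies entered unstandardized and assessed by
   hierarchical R-squared-change F-tests.

# The synthetic-data generator

Real resting-state data cannot be redistributed, so the package ships a
generator (`simulation_config()`, `generate_cohort()`,
`generate_symptoms()`) whose defaults emulate the study design the
pipeline targets: 69 subjects (39 controls, 11 clinical high-risk, 19
first-episode), 185 frames at TR = 2 s, and node series drawn from a
multivariate normal with block-constant correlations — 0.6 within and 0.1
between planted communities. The default 60-node layout plants four
communities: the three DMN subnetworks in the empirically reported sizes
18 (PM), 22 (AT), 8 (MPF), plus 12 non-DMN nodes; all 48 DMN nodes carry
the reference label `"Default mode"`, and node coordinates scatter around
canonical subnetwork centroids so the centroid-based PM/AT/MPF naming is
exercised. Motion is a Gaussian random walk (step SD 0.035 mm; rotation
steps scaled by the 50 mm sphere radius so both contribute equally to FD)
with sporadic 1.5 mm single-frame spikes at rate 0.02/frame; these
settings put mean FD near 0.23 mm, the level reported for retained
subjects in the motivating study.

Two structural choices deserve explanation:

* **The planted whole-brain partition is flat.** At resolution
  gamma = 1.25 on a 60-node graph, modularity always prefers splitting a
  community holding 48 of 60 nodes, whatever intermediate correlation is
  planted between its sub-blocks (the null term grows with the squared
  community strength). The generator therefore plants the three DMN
  subnetworks directly as whole-brain communities, and the DMN node set is
  the union of the communities dominated by the default-mode reference
  label (`identify_dmn(mode = "union")`). On real data, where the DMN is a
  modest fraction of 200+ nodes, the single-community reading
  (`mode = "largest"`, the default) applies.
* **Planted symptom effects are sized for recoverability.** The negative
  score follows
  `beta_mpf_pm * z(MPF,PM) + beta_mpf_at * z(MPF,AT) + beta_fd * meanFD`
  plus Gaussian noise, recentred to a plausible PANSS negative level and
  clipped to the instrument ranges (7-49 for the 7-item subscales, 16-112
  for general). The across-subject SD of the between-subnetwork z values
  is a consequence of the scan geometry (about 0.05 at T = 185); the
  default raw coefficients (-70, -90, noise SD 4.0) therefore implement
  standardized effects near -0.5 and -0.6 — MPF-AT the stronger, matching
  the ordering of the motivating finding — chosen by a power argument so
  that each effect is individually detectable in a 28-patient sample. The
  study's own standardized estimates (-0.16, -0.43, R-squared 0.29) are
  deliberately *not* used as generator truth: effects that weak are not a
  well-posed recovery target at n = 28, so a recovery test built on them
  would measure luck, not correctness. The positive score is generated
  with a tunable correlation to mean FD (default 0.39) and the general
  score is pure noise.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise structure, spatial smoothness,
scanner drift beyond what the DCT basis removes, and site or session
effects. Passing the recovery suite therefore shows the pipeline's
*algorithms* are correct under known structure — not that real
acquisitions satisfy the generator's assumptions. Temporal autocorrelation
is available (`ar_coef`) but defaults to 0, since the downstream
statistics treat frames as exchangeable after filtering.

# Numerical and design choices

* **Signed modularity.** "Modified Louvain" is implemented as
  resolution-parametrized modularity with the asymmetric signed scheme
  (positive part dominant); a `negative = "zero"` mode ignores negative
  weights. Each `louvain_partition()` call runs 20 greedy restarts
  (the first from the classic singleton start, the rest descending from
  random initial partitions, each with randomized sweep order, local moves
  and aggregation until no improvement) and keeps the best Q; on graphs of up to 8 nodes this matches an
  exhaustive enumeration of all set partitions, which the test suite
  checks on a 200-graph battery.
* **Consensus identity across runs.** The 40% stability rule needs a
  notion of "the same community" across runs; the package matches each
  run's communities to the maximum-Q reference run by optimal injective
  assignment on the contingency table (exact permutation search up to 7
  communities, greedy beyond). With `iterations = 1` the consensus reduces
  exactly to a single Louvain run.
* **NMI normalization** uses the mean of the two label entropies. Removed
  nodes are dropped pairwise before computing agreement.
* **Group averaging** is done on raw r values by default (`mode = "z"`
  Fisher-averages instead); profile block means transform-then-average by
  default (`r_first` available) — both orders are exposed because printed
  tables rarely pin down which was used.
* **Elastic-net penalty rule.** Per bootstrap resample the penalty is
  chosen by seeded 10-fold cross-validation on a 100-point logarithmic
  lambda path. The default is the **1-SE rule** (sparsest lambda within
  one standard error of the CV minimum) rather than the CV minimum:
  at n = 28 the CV-minimum rule keeps pure-noise predictors in roughly
  half of resamples, pushing null VIPs toward the 70% threshold and
  yielding per-predictor false-selection rates far above the nominal
  level, while the 1-SE rule keeps null VIPs near 0.2-0.3 and false
  selection in the single digits with no loss of power on planted effects.
  `lambda_rule = "min"` remains available. The solver follows the
  standard convention of measuring the ridge component relative to the
  response's population SD; at alpha = 1 this is exactly the plain lasso
  objective, and the inclusion decisions that VIP counts are unaffected.
  "Included" means a coefficient with magnitude above 1e-12 at the
  selected penalty. Resamples that lose all variance in a predictor are
  redrawn and counted.
* **Degenerate inputs.** Constant node series yield an infinite-tSNR
  sentinel (never excluded by the "below 50" rule); a constant response
  returns all-zero coefficients with a flag; an all-zero connectivity
  matrix yields a flagged single-community result; zero-variance nodes and
  collinear design columns raise errors naming the offender; rank-deficient
  nuisance designs are pruned with a warning (earliest column of any
  dependent set kept). DMN subclustering reports whatever community count
  emerges — three is never forced — and applies the PM/AT/MPF names only
  when there are exactly three (most posterior mean y = PM, most inferior
  remaining = AT, remainder = MPF; the names are cosmetic, membership is
  the tested object).
* **Determinism.** Every stochastic function takes a seed and derives
  independent sub-streams (subject index, bootstrap index, Louvain
  iteration = seed + i), so cohorts, ensembles and VIP vectors are
  bit-reproducible; the RNG state of the calling session is never
  disturbed.

# Problem sizes used in validation

The validation suite runs at the sizes the analysis design states:
demographic t-tests from printed 9-vs-19 summaries; a 200-graph
Louvain-vs-exhaustive battery at 4-8 nodes; a 50-subject, 60-node,
185-frame cohort for consensus-recovery (1000 Louvain iterations at both
resolutions); and 20 + 20 cohorts of 28 patients with B = 500 bootstrap
resamples for selection recovery and null control. The 1000-iteration
consensus runs use 5 restarts per iteration — the ensemble itself
supplies the diversification that single-shot calls get from the default
20 restarts. B = 5000 (the
production default) behaves like B = 500 with tighter VIP estimates; the
scaled-down B is a documented test mode.

# Known limitations

* The pipeline starts from extracted node time series (or tabular
  fixtures); volumetric preprocessing (realignment, normalization,
  smoothing) is assumed done upstream, and no NIfTI extraction is
  performed.
* The greedy modularity optimizer is exact only on small graphs; on large
  graphs the consensus ensemble quantifies, but does not eliminate,
  optimization variability.
* Pooled-variance t-tests assume equal group variances; the package does
  not offer a Welch option because the reproduced statistics pin the
  pooled form.
* VIP-based selection controls inclusion frequency, not familywise error;
  the OLS refit's p-values are conditional on selection and should be read
  descriptively.
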