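---
title: "Methods: EV-proteome signature discovery with evsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV-proteome signature discovery with evsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`evsig` re-implements a biomarker-discovery workflow for plasma
extracellular-vesicle (EV) proteomes: starting from a TMT reporter-intensity
matrix (proteins × samples, log2 scale, with missing values) and a clinical
annotation table, it filters the proteome by group-wise presence, selects
differentially expressed proteins with a volcano rule, ranks biomarkers by
boosted-regression prediction error, classifies four clinical classes with a
hybrid CNN→SVM, builds a logistic multi-marker score, and evaluates the
score by ROC and survival analysis. This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, the
design decisions taken where the workflow was genuinely open, and what the
synthetic-cohort tests do and do not demonstrate.

## Data model

The central container is an `ev_intensity` tibble: one `protein` column of
unique identifiers plus one numeric column per sample, carrying log2
reporter intensities, with `NA` for missing observations (missingness is
never conflated with zero). A scale attribute distinguishes `linear` from
`log2` tables; differential-expression and machine-learning stages refuse
linear input, and `normalize_log2()` is the only path between the scales.
The loader fixes the orientation as proteins-in-rows and rejects matrices
whose columns cannot be matched to annotations rather than guessing a
transpose — silent transposition being the classic omics bug. Missing cells
are written back as empty fields; the literal `NA` is also accepted on
input.

Annotations carry the sample's group (HC, Luminal, HER2, TNBC), recurrence
status (`early` = before 2 years, `late` = within 2–5 years), and optional
RFS/OS times (months) and event flags. `derive_four_class()` maps these to
the classification target: healthy controls → `Normal`; TNBC with any
recurrence → `TNBC_recur`; TNBC without → `TNBC_no_recur`; luminal and HER2
→ `OtherSubtype` regardless of recurrence. The early/late distinction is
deliberately collapsed for classification but retained in the annotations,
where the survival stage still uses the timing information.

## Synthetic cohort generator

The generator exists so every downstream stage is testable without the
original cohort. Its defaults are the study conditions the pipeline assumes:

* 985 proteins × 130 samples, classes 30 Normal / 57 other subtype /
  26 TNBC without recurrence / 17 TNBC with recurrence. The 26/17 split of
  the 43 TNBC patients is not printed for the proteomic set; it extrapolates
  the validation cohort's 13/17 recurrence proportion and is configurable.
* log2 intensities drawn entry-wise from
  Normal(`baseline_mean` + shift(protein, class), sd(protein)), with
  `baseline_mean = 20` and `baseline_sd = 1` log2 units — typical magnitudes
  for TMT reporter data.
* Four planted signature markers (ECM1, MBL2, BTD, RAB5C) with
  `marker_sd = 0.8`. Their cancer-class shifts anchor to the published
  linear fold changes versus healthy controls (2.238, 6.665, 2.337, 5.913),
  carried by the TNBC-without-recurrence class; the other cancer classes are
  scaled per marker (luminal/HER2 between 0.4× and 1.0×; recurrent TNBC
  1.2×–1.6× for ECM1/BTD/RAB5C and 0.4× for MBL2) to reflect the reported
  qualitative pattern — weaker luminal separation, MBL2 lower and BTD/RAB5C
  higher in recurrent disease. These multipliers are a design choice fixed
  once: the source study prints only cancer-versus-control fold changes, so
  the *between-cancer-class* geometry cannot be copied from it. With
  `marker_sd = 0.8` the implied per-marker t statistics for cancer versus
  control are of the same order as the published p values.
* Missingness is missing-completely-at-random at rate 0.1 by default; an
  `intensity` mode makes dropout three times likelier below the per-protein
  mean at the same overall rate, emulating abundance-dependent MS dropout.
* `simulate_survival()` draws exponential event times whose hazard is
  multiplied by `survival_true_hr` (default 4.8) for samples with score
  > 0.5; overall survival is relapse-free survival plus an independent
  exponential post-recurrence time, so RFS ≤ OS holds by construction, and a
  shared exponential censoring time is calibrated to the target censoring
  fraction via h_c = h·c/(1−c). The baseline hazard log(2)/60 per month
  corresponds to a five-year median relapse-free survival in the low-risk
  group.
* `simulate_elisa()` produces log-normal concentrations (pg/mL) for a
  10-control / 30-case panel with case medians at the requested fold of the
  control median (log-scale SD 0.5, a typical immunoassay between-subject
  spread).

What the generator does **not** emulate: TMT batch/plex effects and
reference-channel normalisation (the loader assumes an already
reference-corrected matrix), peptide-to-protein roll-up, correlated protein
modules, non-Gaussian heavy tails, and informative censoring. Passing tests
therefore demonstrate that the *algorithms* behave as specified on data with
the assumed structure — not that the biological signature itself is
validated.

## Presence filters

Two reductions mirror the proteome-narrowing steps of the workflow
(3171 → 2458 → 985 in the source analysis):

* `filter_min_individuals()` keeps a protein if **some** group has at least
  `min_n = 10` samples with observed values (non-strict, "at least").
* `filter_group_presence()` keeps a protein if its observed fraction
  **strictly exceeds** `min_fraction = 0.7` within **every** group.

The phrase "identified in more than 70% of all groups" is ambiguous between
this per-group reading and "in at least 70% of the groups"; the per-group
reading is the default because it yields a completeness guarantee inside
every group being compared, and the alternative is available via
`mode = "fraction_of_groups"`. Both thresholds follow the wording exactly:
"at least 10" is non-strict, "more than 70%" strict. Filters only drop rows;
retained values are never altered, and both filters are monotone in their
thresholds and idempotent (property-tested).

`impute_median()` fills missing entries with the per-protein median over
*all* samples — per-group imputation would leak class labels into the
classifier input. Imputation feeds only the boosting and classification
stages; differential-expression tests always use observed values, because
imputed constants would understate within-group variance.

## Differential expression

`two_group_test()` is Welch's two-sample t-test, two-sided, on observed log2
intensities; the effect is the difference of group means. The volcano rule
flags proteins with raw p < 0.05 and |Δlog2| > 1 (fold change > 2), the
thresholds being strict. The fold change is reported as 2^|Δlog2| with
direction carried by the up/down flags, matching the all-positive convention
of the published marker table. No multiple-testing correction enters the
selection — the original analysis filters on raw p — but a
Benjamini–Hochberg column is emitted for information. The exact Perseus test
variant (Student vs Welch, s0) is not recoverable from the source; Welch
was chosen as the variance-robust default and is recorded in the result's
metadata. Proteins with fewer than two observations in either group are
skipped with a warning at the matrix level (an error would make whole-matrix
scans brittle for no statistical gain).

## LSBoost RMSE ranking

The ranking stage asks, per biomarker: how well does this protein alone
predict the clinical class? Each biomarker x_j is regressed onto the numeric
class code y (Normal = 0, OtherSubtype = 1, TNBC_no_recur = 2,
TNBC_recur = 3) by least-squares gradient boosting with depth-1 regression
stumps: stage-wise, each stump fits the current residuals by the
SSE-minimising split (midpoints of adjacent sorted x values; first best
split wins ties), and is added with learning rate 0.1; 100 learners by
default. Training RMSE is non-increasing by construction, and the fit is
fully deterministic.

Per iteration (50 by default, matching the iteration-distribution display of
the source), a stratified 70/30 split is drawn; each biomarker is fit on the
training part and scored by RMSE on the held-out part — training RMSE would
reward overfitting. Per-biomarker RMSE is the mean over iterations, min–max
normalised across biomarkers to [0, 1] ("normalized RMSE" being otherwise
unspecified), and ranked ascending with ties broken lexicographically by
protein id for reproducibility. The ordinal class code imposes an arbitrary
order; `target = "one_vs_rest"` averages the RMSE over the four binary
indicator targets instead. `rmse_correlation()` correlates the top markers'
per-iteration RMSE vectors (Pearson); whether the source's correlation
display uses iteration RMSE, intensities or residuals is not stated —
iteration RMSE was chosen because it is the quantity the iterations actually
produce. The boosting kernel is compiled (Rcpp) since a 985-biomarker ×
50-iteration scan performs ~5 million stump fits.

## Hybrid CNN→SVM classifier

The classifier follows the two-stage design: a convolutional feature
extractor whose penultimate activations ("activation map") are classified by
an SVM. The network, whose original hyperparameters are not recoverable, is
the smallest architecture that instantiates the design at desk scale: two
1-D convolution blocks over the biomarker axis (kernels 7 then 5, 16 then 32
channels, ReLU, max-pool 2), a dense layer of 64 units (the activation map),
and a softmax head used only for training. It is trained full-batch with
Adam (rate 2e-3, 150 epochs, weight decay 1e-3, He initialisation), all
seeded; forward and backward passes are vectorised im2col/BLAS operations,
and the gradients are verified against numerical differentiation in the test
suite. Features are standardised with training-split statistics only
(leakage control). Panels shorter than the convolutional minimum (input too
short for kernel–pool–kernel–pool) use a dense two-layer extractor instead,
with a notice; the default pipeline feeds the top-4 ranked markers — the
workflow applies the CNN-SVM to the top biomarkers in ascending RMSE — so
the dense path is what runs there.

The SVM is an RBF-kernel one-vs-one multiclass machine (e1071); per-class
one-vs-rest scores for ROC come from its Platt-calibrated probabilities.
Reports include the confusion matrix (rows = truth), per-class TPR/FNR,
overall accuracy (trace/total), macro accuracy, and per-class one-vs-rest
AUC by the Mann–Whitney statistic. The source reports training-set results;
this package reports held-out metrics as primary and training metrics
secondarily, because training accuracy of a flexible model is not evidence
of generalisation. With 130 samples the held-out split has 39 samples (5 in
the smallest class), so single-split accuracies carry a binomial standard
error of about 0.065 and per-class AUCs are correspondingly noisy; the
classifier's achievable accuracy is bounded by the planted-marker signal
(cross-class Mahalanobis distances of roughly 2.4–3.6 in the default
generator), which places the optimum in the low-to-mid 0.8s — the same
regime as the published 84.7%.

## Marker score and combination search

`fit_marker_score()` fits maximum-likelihood logistic regression of the
binary outcome on a marker panel. The inclusion rule is a **single backward
pass**: fit, drop all markers with Wald p > 0.1, refit once (the source
describes one exclusion criterion, not a stepwise protocol; `iterate = TRUE`
gives the stepwise variant). The panel is never emptied — the most
significant marker survives. Perfect or near separation (non-convergence,
|β| > 15, or vanishing deviance) is flagged and the coefficients come from a
weak ridge penalty (glmnet, λ = 1e-3) instead of a divergent fit. The score
is the fitted probability; `risk_classify()` applies the strict > 0.5
high-risk rule.

`evaluate_combinations()` enumerates all 2^k − 1 non-empty subsets of ≤ 10
candidates (k ≤ 15 hard limit), fits each panel, scores the samples, and
computes AUC with DeLong SE. The best panel maximises AUC with ties broken
by minimal SE, then by smaller panel, then lexicographically — exactly one
winner. Within the search each subset is evaluated **as listed**
(`exclusion_p = 1`): applying the backward exclusion inside every subset
would collapse nested panels onto identical effective models and produce
exact AUC ties, making "which combination is best" ill-posed; the exclusion
rule belongs to the final score-model construction. When a split is
supplied, panels are fit on the training part and AUCs measured on the test
part — the honest variant used for null calibration, since in-sample AUCs of
fitted models are optimistic by construction. Whether the published
per-combination equations were fit on a split or on all samples is not
stated; without a split the search fits on all rows, matching the
in-sample flavour of the published combination table.

`normalize_to_control_median()` implements the immunoassay branch: each
marker's concentrations are divided by that marker's median among controls,
putting heterogeneous assay scales on a common fold-of-control axis.

## ROC and survival machinery

`roc_auc()` computes the empirical ROC over all thresholds; the AUC is the
Mann–Whitney concordance statistic with midrank tie handling, which equals
the trapezoidal area under the curve exactly (asserted to 1e-12 in tests).
Two standard errors are reported — Hanley–McNeil (moment-based) and DeLong
(placement values) — and the 95% CI is DeLong-based, clipped to [0, 1]; the
commercial package used by the source does not name its CI method, so both
are labelled in the output. `sensitivity_at_specificity()` reads the curve
at the most permissive threshold whose specificity still meets the target
(conservative: no interpolation beyond observed operating points) and
attaches a stratified bootstrap percentile CI (2000 resamples, seeded).

Survival uses the survival package throughout: product-limit Kaplan–Meier
curves, the two-sample log-rank chi-square (1 df), and Cox partial
likelihood with Efron tie handling and Wald CIs on the log scale. A group
without events yields a flagged non-converged result rather than a crash.
`survival_by_score()` dichotomises at the strict 0.5 rule by default, with a
median split as option; when the fixed cutoff leaves one risk group empty —
which happens whenever a diagnostic score saturates near 1 for all cases —
it falls back to a median split and records the applied rule, keeping the
pipeline well-defined on degenerate score distributions.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/load → preprocess → volcano → rank →
classify → score → evaluate → survival under a single configuration whose
defaults are the workflow's thresholds: p = 0.05, |log2 FC| > 1, presence
> 0.7, ≥ 10 individuals, 70/30 split, 50 ranking iterations, top 10 markers,
exclusion p = 0.1, fixed specificity 0.95, risk cutoff 0.5. A global seed
fans out to stage-specific derived seeds, so stages are individually
reproducible; reruns with identical configuration are bit-identical (the
manifest omits wall-clock timings for this reason and stores artifact paths
relative to the output directory). Stage artifacts are plain TSV/JSON and
reusable; automatic resume-from-stage is not implemented. No shell entry
point is shipped — the package's functions, this vignette and
`scripts/acceptance.R` are the interface an R analyst would use.

## Problem sizes and numerical choices

The test suite exercises the full 985 × 130 conditions where the scientific
claim depends on them (marker recovery, classifier behaviour, type-I
control, determinism) and scales everything else down to fixtures of 6–60
proteins and 20–44 samples chosen so the whole suite completes in a few
minutes. Oracle tests freeze expected values computed by independent brute
force: exhaustive pairwise concordance for AUC, threshold sweeps for
sensitivity at fixed specificity, hand-counted confusions, the
observed-minus-expected form of the log-rank statistic, and textbook Welch
formulas, at tolerances of 1e-9 to 1e-12. Numerical edge cases are decided
explicitly: stump splits break ties toward the smallest midpoint; rank ties
break lexicographically; degenerate zero-variance groups give p = 1 when
means agree; zero-variance iteration RMSE yields a flagged undefined
correlation rather than NaN propagation; probability floors (1e-12) guard
the cross-entropy; and the sigmoid is evaluated directly (scores saturate to
0/1 in the extreme-intercept limit).

## Known limitations

* The MATLAB-specific internals of the original LSBoost-CNN-SVM
  ("characteristic equations", "parallel-learning functions", exact CNN
  hyperparameters) are not recoverable from the text; this package
  implements the stated statistical content — per-biomarker boosted
  regression ranked by held-out RMSE feeding a CNN→SVM classifier — with
  documented choices where the text is silent.
* Held-out metrics on a 130-sample cohort are intrinsically noisy; claims at
  the published precision (e.g. a single accuracy to three digits) are not
  reproducible at this scale, and the tests assert distributional behaviour
  across seeds instead.
* The survival generator's exponential model satisfies proportional hazards
  by construction; it validates the estimators, not the proportional-hazards
  assumption on real cohorts.
* Multivariable Cox with clinical covariates, competing risks, FDR-based
  DEP selection and pathway enrichment are out of scope.
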