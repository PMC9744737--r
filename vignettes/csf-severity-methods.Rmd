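---
title: "Methods: CSF proteomic models of MS severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF proteomic models of MS severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and rationale

`csfseverity` implements an analysis pipeline for modeling the severity of
multiple sclerosis (MS) from cerebrospinal-fluid (CSF) aptamer proteomics.
The measurement substrate is a SomaScan-style panel: one relative
fluorescence unit (RFU) readout per analyte (SOMAmer), analyzed throughout
on the natural-log scale. Severity is understood as the *rate* of
disability accumulation — operationalized by age-anchored clinical scales
such as MS-DSS, and by a brain-volume analogue — rather than accumulated
disability itself. The pipeline's stages are:

1. **Physiological adjustment** of every analyte for age and sex, anchored
   to regressions fitted in healthy volunteers (HV) only.
2. A **proteomic aging clock** (elastic net) as a check that MS does not
   simply accelerate global physiological aging.
3. **Severity outcomes**: the brain-volume-deficit (BVD) residual and the
   intraclass correlation (ICC) quantifying how stable a severity scale is
   within a patient.
4. A **univariate Spearman/FDR screen** of analytes against outcomes.
5. The core **severity models**: all pairwise analyte ratios plus singles,
   pruned by iterative random-forest importance elimination with an
   out-of-bag (OOB) error cut, and refitted as one large final forest.
6. **Evaluation** on an independent cohort (Spearman rho, $R^2$, Lin's
   concordance correlation coefficient), plus cohort-balance tests.
7. **Heterogeneity**: two-way Ward clustering of the model-selected
   analytes into protein modules and patient clusters.

Every stage is exercisable on synthetic cohorts with planted ground truth
(`simulate_cohort()`), which is how the test suite validates the pipeline.

# Models and estimators

## HV-anchored age/sex adjustment

Disease cohorts confound age with disease stage (progressive patients are
older). Regressing age out *within the MS cohort* would therefore delete
disease signal along with physiological aging. Instead, for each analyte
$a$ the joint HV regression

$$\log y_{a} = \beta_{0a} + \beta_{\mathrm{age},a}\,\mathrm{age} +
\beta_{\mathrm{sex},a}\,\mathbb{1}(\mathrm{female}) + \varepsilon$$

is fitted on healthy volunteers only, and the *HV-estimated* component is
subtracted from every sample (HV and MS alike), re-centred at the HV mean
age and the HV sex composition so values stay on an interpretable log-RFU
scale:

$$\tilde y = y - \hat\beta_{\mathrm{age}}(\mathrm{age} - \overline{\mathrm{age}}_{HV})
 - \hat\beta_{\mathrm{sex}}(\mathbb{1}(F) - \bar s_{HV}).$$

Any MS-specific excess (e.g. a disease process that rises with disease
duration) survives the subtraction by construction; the tests verify this
on planted MS-excess slopes.

Which analytes get adjusted is decided by a two-tier screen that spends the
small HV cohort's p-values frugally:

* **Tier 1** starts from analytes already flagged significant in a large
  external serum reference study, and requires (A) an HV-CSF association
  at $p < 0.05$ whose direction matches the serum reference, and (B) an
  MS-cohort association with Benjamini–Hochberg adjusted $p < 0.05$ within
  the candidate family, per covariate. MS-vs-HV slope-sign discordance is
  recorded (it marks candidate disease processes) but does not block
  adjustment: the HV component is physiological either way.
* **Tier 2** screens the analytes absent from the reference with a
  Bonferroni family-wise criterion ($p < 0.05/m$) in HV, per covariate.

The BH choice in criterion B, and treating analytes selected for both
covariates in a single joint fit, are package decisions where the source
procedure leaves the multiplicity family unnamed; both are configurable.

## Proteomic aging clock

An elastic net ($\alpha = 0.5$) predicts chronological age from
standardized log-RFU values, trained on HV only. Standardization means/SDs
and the penalty come from the training data alone; with ~24 HV samples,
leave-one-out cross-validation is the only stable choice, with the
one-standard-error rule as the default penalty pick (the plain CV minimum
is available via `lambda_rule = "min"`). Delta age (predicted minus
observed) is contrasted between diagnostic groups by two-sided Wilcoxon
rank-sum tests with BH adjustment. The clock consumes unadjusted values by
default — it models age itself, so removing age effects first would be
self-defeating; this is configurable by simply passing the adjusted panel.

## Severity outcomes

**BVD severity** is the residual of $1 - \mathrm{BPFr}$ (BPFr = brain
parenchymal fraction) regressed on age over the MS baseline cohort:
positive values mean more CNS tissue loss than equally aged peers. HV
samples are excluded from this fit; residuals have mean zero and zero age
covariance over the fitting cohort by construction.

**ICC** uses the one-way random-effects form: subjects are random, visits
exchangeable — a two-way form would treat visit index as a crossed factor,
which repeated clinic visits are not. From the one-way ANOVA decomposition,

$$\widehat{\mathrm{ICC}} = \frac{MS_B - MS_W}{MS_B + (k_0 - 1) MS_W},
\qquad k_0 = \frac{N - \sum_i k_i^2 / N}{n_{\mathrm{subjects}} - 1},$$

with $k_0$ the standard unbalanced-design coefficient. The estimate may be
negative when the between-subject variance estimate is non-positive; if all
values are identical the result is NaN with a warning.

## Ratio features and random-forest backward elimination

All $p$ adjusted analytes plus all $p(p-1)/2$ unordered pairwise ratios
form the candidate pool (`expand_ratios()`); on the log scale a ratio is a
difference, stored once per pair with the lexicographically smaller ID as
numerator. Elimination proceeds by:

1. fitting 10 regression forests (distinct derived seeds) on the current
   pool, recording the mean and SD of their OOB mean squared errors;
2. averaging their node-impurity (variance-reduction) importances;
3. dropping the `max(1, floor(0.1 p))` least-important features, ties
   broken lexicographically for determinism;
4. repeating until 3 features remain.

The final model is refitted at the cut point with `ntree = 40000` and
`mtry = 3\sqrt{p}` (rounded half up, clipped to $[1, p]$). The selection
phase uses a smaller tree count (default 200) — its job is only to rank
features stably, and ten forests are averaged per step.

**Cut rule.** The default takes the step with the *minimum* mean OOB error
— the natural reading of pruning until the OOB error has minimized. A
one-standard-error alternative (`cut_rule = "1se"`: smallest
feature count within one SD of the minimum) is provided but not default:
with only ten forests per step the SD band is wide, and in simulation the
1-SE rule regularly collapsed models to three or four features and
destroyed independent-cohort performance.

OOB evaluation of training performance is still optimistic here, because
features were selected using OOB error on the same samples; the honest
quantity is the independent-cohort evaluation, and the tests assert the
expected overfit signature (training rho > validation rho in every seed).

## Evaluation statistics

$R^2$ is the squared Pearson correlation of observed vs predicted (the
simple-regression $R^2$, symmetric in its arguments). Lin's CCC uses
population (divide-by-$n$) moments,

$$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

so $|\mathrm{CCC}| \le |r|$ with equality only when the fit is on the
identity line. Cohort balance uses a Yates-corrected 2×2 chi-square for sex
— the corrected form is the convention for small clinical 2×2 tables, and
the uncorrected statistic gives visibly different p-values at these cohort
sizes — and two-sided Wilcoxon rank-sum tests for quantitative variables.

## Heterogeneity clustering

Analyte values (z-scored per analyte over the MS cohort) of the analytes
selected by the severity models are clustered in both directions with
Ward's minimum-variance linkage on Euclidean distances in the squared-
update convention (`hclust` method `"ward.D2"`); the sample tree is cut at
7 patient clusters and the analyte tree at 4 protein modules by default.
Hierarchical clustering is deterministic; equal merge costs follow
`hclust`'s lowest-index-first rule.

# The synthetic cohort generator

`simulate_cohort()` draws an HV + MS cohort with planted, recorded truth:

* **Cohort structure**: 24 HV (ages uniform 20–70) and 129 MS split
  37/31/61 into RRMS/SPMS/PPMS with subtype-shifted normal ages
  (40.9/52.3/54.8 ± 11.1/9.0/7.9, truncated to 18–75) — the size and age
  structure of a deeply phenotyped single-center MS cohort, with the age
  confounding (progressive patients older) that the adjustment stage must
  handle; a validation-like configuration (33/24/41) shares the same
  analyte truth via the `truth` argument.
* **Analyte classes**: age-concordant (same slope in HV and MS, in the
  serum reference), age-discordant (negative HV slope, positive MS slope),
  sex-shifted, tier-2 age analytes absent from the reference, reference
  *decoys* (serum-significant but no CSF effect — they exercise the
  screen's false-positive control), severity-module members, and pure
  noise. Default slopes are 0.02 log-RFU/year and 0.5 log-RFU sex shifts
  against a residual SD of 0.25 — roughly 5 standard errors at the HV
  cohort size, i.e. clearly detectable but not caricatured.
* **Severity**: module members load (0.3) on a shared per-module latent
  factor; the latent severity is the weighted sum of centred module-analyte
  values plus Gaussian noise. The noise SD is solved in closed form so that
  the strongest single analyte has a chosen population correlation with
  severity (`target_marker_rho = 0.35`), reproducing the weak-single-marker
  regime in which aggregation is the only way to a strong model.
* **Brain volume**: $1-\mathrm{BPFr} = 0.10 + 0.0015\,\mathrm{age} +
  \mathrm{deficit} + \mathrm{noise}$, the per-subject deficit correlated
  0.6 with latent severity in MS.
* **Longitudinal severity** (separate generator): subject random
  intercepts plus visit noise; the default variance components 9 and 1
  plant a population ICC of 0.90, the stability regime of a severity scale
  whose repeated measurements are nearly interchangeable.

Two structural choices deserve explanation. First, the default severity
structure is four disjoint modules of three analytes: correlated modules
are what the heterogeneity stage is supposed to recover. Second, the
end-to-end severity-model recovery scenario instead plants six *mutually
independent* driver analytes. With strongly correlated within-module
drivers, two artifacts appear: the aggregate signal ceiling collapses
toward the best single marker — whereas the regime this scenario emulates
is precisely one where independent validation of the aggregate model
(rho ≈ 0.4–0.5) clearly exceeds every single marker (rho < 0.4), which
requires weakly correlated informative markers — and, with exactly equal
member weights, the
within-module log-ratio of two drivers is *exactly* orthogonal to
severity, a degeneracy no real cohort exhibits. Independent drivers avoid
both while keeping every driver individually weak.

What the generator does **not** emulate: assay artifacts (plate and
hybridization batch effects), treatment effects, non-linear age trends,
heavy-tailed RFU noise, missing values (inputs with missing analyte values
are rejected rather than imputed, as SomaScan panels are complete in
practice), and correlation between the age/sex classes and the severity
modules (classes are disjoint by construction). Passing tests therefore
demonstrate that the estimators and the selection machinery recover what
was planted under clean Gaussian conditions — not that the pipeline is
robust to assay pathology.

# Numerical and design details

* **Seeds**: one master seed; each stochastic stage derives child seeds via
  `derive_seed()` (a multiplicative hash mod $2^{31}-1$), so stages are
  individually reproducible and forests within a step are independent but
  deterministic.
* **mtry rounding**: `3*sqrt(p)` is rarely integer; rounded half up, then
  clipped to $[1, p]$.
* **Importance ties** during elimination break lexicographically by feature
  ID; **merge-cost ties** in clustering follow `hclust`'s deterministic
  rule — both so that re-runs and cross-platform runs agree.
* **Tree-split invariance**: regression-tree splits depend only on the
  ordering of feature values, so storing ratios as log differences rather
  than raw quotients does not change fitted partitions (up to
  floating-point ties between near-equal candidate splits).
* **Degenerate inputs** fail loudly: constant outcomes, constant
  covariates, BPFr outside (0,1), non-positive raw RFU, and missing values
  are fatal; constant analytes in correlation or z-score contexts are
  dropped or set NaN with a warning.
* **Sex coding**: two-level F/M mapped to an indicator (female = 1); the
  adjustment centres the indicator at the HV composition, making it
  symmetric in the coding. The reference level is recorded in the results
  manifest.

# Problem sizes used by the test suite

The package's own validation runs at desk scale, chosen to exercise every
code path on realistic proportions: panels of 60 analytes (1,830 features
after ratio expansion) with 24 HV + 129 MS training and 98 MS validation
samples for the end-to-end property (10 seeds); 20-seed batteries for the
screen's sensitivity/specificity, the adjustment's excess-preservation, and
the clock's null calibration; 500 subjects × 5 visits for ICC recovery;
selection forests of 200 trees and final forests of 2,000 trees in the
end-to-end property (the production default remains 40,000). The
full-platform width (1,305 analytes, 852,165 features) is validated
arithmetically rather than by materializing the matrix.

# Known limitations

* The OOB-based cut point is selection-biased; treat training metrics as
  descriptive and rely on independent-cohort evaluation.
* The elastic-net clock fixes $\alpha = 0.5$; at HV cohort sizes around 24
  there is no information to tune the mixing parameter honestly.
* The univariate screen assumes baseline-only MS samples (CSF is sampled
  at baseline); longitudinal visits feed only the ICC.
* Enrichment statistics are out of scope: the package exports ranked gene
  lists in the formats external services expect, nothing more.
* With `cut_rule = "1se"` and few forests per step, models can collapse to
  the floor; keep the default unless the OOB trace is visibly flat.
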