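# csfseverity

Modeling multiple-sclerosis (MS) severity from cerebrospinal-fluid (CSF)
aptamer proteomics.

## The problem

MS destroys central-nervous-system tissue at very different speeds in
different patients, and no single CSF protein tracks that speed well: the
best individual markers correlate only weakly with severity scales.
`csfseverity` implements, as a tested and reusable R pipeline, the analysis
strategy of aggregating a full SomaScan-style CSF panel (log-transformed
relative fluorescence units, RFU) into machine-learning models of severity
that validate in an independent cohort — together with every supporting
stage such an analysis needs. It is written for biostatisticians and
computational neuroimmunologists working with proteomic panels and
age-anchored severity outcomes (MS-DSS, brain-volume deficit).

The pipeline's stages:

* **Healthy-volunteer-anchored adjustment** — per-analyte OLS
  `log RFU ~ age + sex` fitted in healthy volunteers (HV) only, with a
  two-tier screen (serum-reference-anchored tier at α = 0.05 with FDR in
  the MS cohort; Bonferroni tier for analytes absent from the reference)
  deciding which analytes to adjust. Subtracting only the *physiological*
  component preserves MS-specific excess, unlike regressing age out within
  the patient cohort.
* **Proteomic aging clock** — elastic net (α = 0.5, leave-one-out CV)
  predicting chronological age from HV panels, with Wilcoxon/FDR delta-age
  group contrasts.
* **Severity outcomes** — brain-volume-deficit severity (residual of
  `1 − BPFr` on age in MS baselines) and the one-way random-effects
  intraclass correlation `ICC = (MSB − MSW) / (MSB + (k0 − 1) MSW)`
  quantifying intra-individual stability of longitudinal severity.
* **Univariate screen** — Spearman rho with Benjamini–Hochberg q-values per
  outcome, plus ranked gene-list exports for external enrichment tools.
* **Severity forests** (the core) — all `p + p(p−1)/2` single + pairwise
  ratio features (log differences), pruned by iterative backward
  elimination: 10 random forests per step, averaged node-impurity
  importance, bottom 10% dropped until 3 features remain, cut at the
  minimum mean out-of-bag error; final forest with `ntree = 40,000`,
  `mtry = 3√p`.
* **Evaluation** — Spearman rho, R², Lin's concordance correlation
  coefficient on an independent cohort; cohort-balance tests.
* **Heterogeneity** — two-way Ward (`ward.D2`) clustering of z-scored,
  model-selected analytes into protein modules × patient clusters.

A synthetic-cohort generator (`simulate_cohort()`) plants age/sex effects,
severity-driving analytes, brain-volume trends and longitudinal variance
components with recorded ground truth, so the whole pipeline is verifiable
end to end. See the methods vignette
(`vignettes/csf-severity-methods.Rmd`) for the models, assumptions and
design decisions.

## Worked example

Train on a synthetic cohort of 24 HV + 129 MS with six planted severity
drivers among 60 analytes, validate on an independent 98-sample MS cohort
sharing the same analyte truth:

```r
library(csfseverity)

cfg_train <- simulation_config(module_sizes = rep(1, 6), seed = 1)
cfg_valid <- simulation_config(n_ms = c(rrms = 33, spms = 24, ppms = 41),
                               module_sizes = rep(1, 6), seed = 2)
train <- simulate_cohort(cfg_train)
valid <- simulate_cohort(cfg_valid, truth = train$truth)

hv_assoc <- fit_cohort_regressions(train$panel, train$metadata, "HV")
ms_assoc <- fit_cohort_regressions(train$panel, train$metadata, "MS")
tier1 <- screen_tier1(train$reference, hv_assoc, ms_assoc)
tier2 <- screen_tier2(setdiff(colnames(train$panel),
                              train$reference$analyte_id), hv_assoc)
models <- build_adjustment_models(train$panel, train$metadata, tier1, tier2)
adj_train <- adjust_panel(train$panel, train$metadata, models)
adj_valid <- adjust_panel(valid$panel, valid$metadata, models)

ms_tr <- train$metadata$cohort == "MS"
fit <- train_severity_model(expand_ratios(adj_train[ms_tr, ]),
                            train$metadata$msdss_baseline[ms_tr],
                            outcome_name = "msdss_baseline",
                            ntree_selection = 200, ntree_final = 2000,
                            seed = 1)
fit
#> CSF severity random forest ('msdss_baseline')
#>   28 selected features over 26 unique analytes; ntree = 2000, mtry = 16
#>   elimination: 62 steps from 1830 features; OOB cut ('min' rule) at 28 features (OOB MSE 0.5234)
summary(fit)
#> Training (OOB) performance for 'msdss_baseline':
#>   Spearman rho 0.773 (p = 6.57e-27), R^2 0.604, CCC 0.691, n = 129
```

The elimination started from 1,830 features (60 singles + 1,770 ratios),
kept 28 at the out-of-bag error minimum, and the out-of-bag training
correlation is rho = 0.773. Validation in the independent cohort:

```r
ms_va <- valid$metadata$cohort == "MS"
pred <- predict(fit, adj_valid[ms_va, ])
ev <- evaluate_predictions(valid$metadata$msdss_baseline[ms_va], pred)
unlist(ev[c("n", "spearman_rho", "r_squared", "ccc")])
#>            n spearman_rho    r_squared          ccc
#>     98.00000      0.55444      0.35449      0.48791

drivers <- subset(train$truth$analytes, severity_weight != 0)$analyte_id
intersect(fit$analytes, drivers)
#> [1] "APT0029" "APT0030" "APT0031" "APT0032" "APT0033" "APT0034"
```

The model transfers to the independent cohort (rho = 0.554, noticeably
below the selection-biased training value — the expected overfit
signature) and its 26 unique analytes contain all six planted severity
drivers. `run_pipeline()` chains the same stages — adjustment, clock,
outcomes, screen, model, clustering — from a single
`pipeline_config()`, and `write_results_bundle()` emits the tables plus a
manifest with the configuration hash and seed.

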