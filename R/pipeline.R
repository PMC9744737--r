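#' Run the full CSF severity analysis pipeline
#'
#' End-to-end orchestration: (1) HV/MS association regressions, the two-tier
#' screen and HV-anchored age/sex adjustment; (2) the proteomic aging clock
#' with delta-age contrasts; (3) the brain-volume-deficit outcome and, when
#' longitudinal visits are available, the one-way ICC of the baseline
#' severity outcome; (4) the univariate Spearman/FDR screen; (5) ratio
#' expansion and random-forest severity models per outcome, trained on the
#' training split and evaluated on the validation split; (6) bimodal
#' heterogeneity clustering over the models' selected analytes.
#'
#' The training/validation split is taken from a metadata `split` column
#' (`"training"`/`"validation"`) when present; otherwise MS samples are
#' split at random (seeded) with `train_fraction`.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with `panel`, `metadata`, `reference` (e.g.
#'   from [simulate_cohort()]); read from the configured paths when NULL.
#' @param outcome_cols severity outcome columns to model.
#' @param train_fraction fraction of MS samples assigned to training when no
#'   `split` column exists.
#' @return list with the adjusted panel, association and screen tables,
#'   clock, outcomes, fitted models, evaluation reports and cluster
#'   assignments.
#' @export
run_pipeline <- function(config, data = NULL,
                         outcome_cols = "msdss_baseline",
                         train_fraction = 129 / 227) {
  if (is.null(data)) data <- read_inputs(config)
  panel <- data$panel
  md <- data$metadata
  if (is.null(md$sex_f)) md$sex_f <- as.numeric(md$sex == "F")

  hv_assoc <- fit_cohort_regressions(panel, md, "HV")
  ms_assoc <- fit_cohort_regressions(panel, md, "MS")
  tier1 <- screen_tier1(data$reference, hv_assoc, ms_assoc,
                        alpha = config$tier1_alpha)
  ref_ids <- unique(data$reference$analyte_id[data$reference$significant])
  tier2 <- screen_tier2(setdiff(colnames(panel), ref_ids), hv_assoc,
                        family_alpha = config$tier2_alpha)
  models <- build_adjustment_models(panel, md, tier1, tier2)
  adjusted <- adjust_panel(panel, md, models)
  message(sprintf("adjusted %d analytes (%d tier-1, %d tier-2)",
                  nrow(models), sum(models$tier == 1), sum(models$tier == 2)))

  hv <- md$cohort == "HV"
  clock <- train_age_clock(panel[hv, , drop = FALSE], md$age[hv],
                           seed = derive_seed(config$seed, 1L))
  predicted_age <- predict(clock, panel)
  delta_contrasts <- tryCatch(
    compare_delta_age(predicted_age, md$age, md$subtype),
    error = function(e) NULL)

  baseline <- md$visit_index == 1
  ms_base <- md$cohort == "MS" & baseline
  bvd <- NULL
  if ("bpfr" %in% names(md) && any(!is.na(md$bpfr[ms_base]))) {
    bvd <- compute_bvd_severity(md$bpfr, md$age, ms_base)
    md$bvd_severity <- bvd$bvd_severity
    outcome_cols <- union(outcome_cols, "bvd_severity")
  }
  icc <- NULL
  if (any(duplicated(md$subject_id))) {
    icc <- compute_icc(data.frame(subject_id = md$subject_id,
                                  severity = md[[outcome_cols[1]]]))
  }

  outcomes <- md[ms_base, intersect(outcome_cols, names(md)), drop = FALSE]
  screen <- correlate_outcomes(adjusted[ms_base, , drop = FALSE], outcomes)

  if ("split" %in% names(md)) {
    train_mask <- ms_base & md$split == "training"
    valid_mask <- ms_base & md$split == "validation"
  } else {
    set.seed(derive_seed(config$seed, 2L))
    ms_idx <- which(ms_base)
    tr <- sample(ms_idx, round(train_fraction * length(ms_idx)))
    train_mask <- seq_len(nrow(md)) %in% tr
    valid_mask <- ms_base & !train_mask
  }
  feats_train <- expand_ratios(adjusted[train_mask, , drop = FALSE])
  severity_models <- list()
  evaluation <- list()
  for (oc in names(outcomes)) {
    y_tr <- md[[oc]][train_mask]
    ok <- !is.na(y_tr)
    fit <- train_severity_model(
      feats_train[ok, , drop = FALSE], y_tr[ok], outcome_name = oc,
      n_forests_per_step = config$n_forests_per_step,
      drop_fraction = config$drop_fraction, floor = config$floor,
      ntree_selection = config$ntree_selection,
      ntree_final = config$ntree_final, cut_rule = config$cut_rule,
      seed = derive_seed(config$seed, 10L + match(oc, names(outcomes))))
    severity_models[[oc]] <- fit
    y_va <- md[[oc]][valid_mask]
    ok_va <- !is.na(y_va)
    pred_va <- predict(fit, adjusted[valid_mask, , drop = FALSE][ok_va, , drop = FALSE])
    evaluation[[oc]] <- list(
      training = evaluate_predictions(md[[oc]][train_mask][ok],
                                      fit$oob_predictions, "training"),
      validation = evaluate_predictions(y_va[ok_va], pred_va, "validation"))
  }

  selected_analytes <- sort(unique(unlist(lapply(severity_models,
                                                 `[[`, "analytes"))))
  clustering <- NULL
  if (length(selected_analytes) >= config$k_modules &&
      sum(ms_base) >= config$k_patients) {
    z <- zscore_matrix(adjusted, selected_analytes, ms_base)
    clustering <- cluster_bimodal(z, k_patients = config$k_patients,
                                  k_modules = config$k_modules)
    clustering$summary <- summarize_clusters(clustering, md, z)
  }

  list(adjusted_panel = adjusted, hv_assoc = hv_assoc, ms_assoc = ms_assoc,
       tier1 = tier1, tier2 = tier2, adjustment_models = models,
       clock = clock, predicted_age = predicted_age,
       delta_contrasts = delta_contrasts, bvd = bvd, icc = icc,
       screen = screen, severity_models = severity_models,
       evaluation = evaluation, clustering = clustering,
       train_mask = train_mask, valid_mask = valid_mask)
}
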