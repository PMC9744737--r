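#' Per-analyte age and sex regressions within a cohort
#'
#' Fits, for every analyte, the ordinary least squares model
#' `log RFU ~ age + I(female)` over the samples of one cohort, and returns
#' one association record per analyte and covariate with the two-sided
#' coefficient p-value. All analytes share the design matrix, so the fits
#' are computed in a single QR decomposition.
#'
#' @param panel samples x analytes log-RFU matrix.
#' @param metadata metadata aligned to `panel` rows (needs `cohort`, `age`,
#'   `sex_f`).
#' @param cohort `"HV"` or `"MS"`: which samples to fit on.
#' @return data.frame with `analyte_id`, `covariate`, `cohort`,
#'   `coefficient`, `se`, `t`, `p_value`, `direction`.
#' @export
fit_cohort_regressions <- function(panel, metadata, cohort = c("HV", "MS")) {
  cohort <- match.arg(cohort)
  stopifnot(nrow(panel) == nrow(metadata))
  keep <- metadata$cohort == cohort
  if (sum(keep) < 3) stop("need at least 3 samples in cohort ", cohort)
  Y <- panel[keep, , drop = FALSE]
  age <- metadata$age[keep]
  sex_f <- metadata$sex_f[keep]
  if (stats::var(age) == 0) stop("covariate 'age' is constant in cohort ", cohort)
  if (stats::var(sex_f) == 0) stop("covariate 'sex' is constant in cohort ", cohort)
  X <- cbind(intercept = 1, age = age, sex = sex_f)
  qx <- qr(X)
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  out <- lapply(c(age = 2L, sex = 3L), function(k) {
    se <- sqrt(sigma2 * xtx_inv[k, k])
    tval <- coefs[k, ] / se
    data.frame(analyte_id = colnames(Y),
               covariate = c("age", "sex")[k - 1L],
               cohort = cohort,
               coefficient = unname(coefs[k, ]), se = unname(se),
               t = unname(tval),
               p_value = unname(2 * stats::pt(-abs(tval), df)),
               direction = unname(sign(coefs[k, ])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Pull the record for one covariate as a named lookup by analyte.
assoc_lookup <- function(assoc, cv) {
  a <- assoc[assoc$covariate == cv, , drop = FALSE]
  rownames(a) <- a$analyte_id
  a
}

#' Tier-1 screen: reference-anchored age/sex associations
#'
#' Among analytes flagged significant in the external serum reference, selects
#' those with (A) a significant HV-CSF association (`p < alpha`) whose
#' direction matches the reference direction, and (B) an MS-cohort
#' association with Benjamini-Hochberg adjusted `p < alpha` (adjustment
#' within the candidate family, per covariate). Each candidate is also
#' classified as MS-concordant or MS-discordant by comparing the signs of
#' the MS and HV coefficients; discordance does not block selection (a
#' discordant analyte still carries a physiological HV component worth
#' removing).
#'
#' @param reference reference table (see [read_reference()]).
#' @param hv_assoc,ms_assoc association tables from
#'   [fit_cohort_regressions()] on the HV and MS cohorts.
#' @param alpha per-test level (default 0.05).
#' @return data.frame, one row per candidate analyte x covariate, with
#'   `selected` and `ms_concordant_with_hv` flags.
#' @export
screen_tier1 <- function(reference, hv_assoc, ms_assoc, alpha = 0.05) {
  ref <- reference[reference$significant, , drop = FALSE]
  out <- list()
  for (cv in c("age", "sex")) {
    cand <- ref[ref$covariate == cv, , drop = FALSE]
    if (!nrow(cand)) next
    hv <- assoc_lookup(hv_assoc, cv)
    ms <- assoc_lookup(ms_assoc, cv)
    absent <- setdiff(cand$analyte_id, rownames(hv))
    if (length(absent)) {
      warning("reference analytes absent from panel, skipped: ",
              paste(absent, collapse = ", "))
      cand <- cand[!cand$analyte_id %in% absent, , drop = FALSE]
      if (!nrow(cand)) next
    }
    hv <- hv[cand$analyte_id, ]
    ms <- ms[cand$analyte_id, ]
    crit_a <- hv$p_value < alpha & hv$direction == sign(cand$coefficient)
    ms_adj <- bh_adjust(ms$p_value)
    crit_b <- ms_adj < alpha
    out[[cv]] <- data.frame(
      analyte_id = cand$analyte_id, covariate = cv,
      ref_direction = sign(cand$coefficient),
      hv_coefficient = hv$coefficient, hv_p = hv$p_value,
      ms_coefficient = ms$coefficient, ms_p = ms$p_value,
      ms_adjusted_p = ms_adj,
      selected = crit_a & crit_b,
      ms_concordant_with_hv = ms$direction == hv$direction,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tier-2 screen: Bonferroni discovery outside the reference
#'
#' For analytes not prioritized by the serum reference, selects those whose
#' HV-CSF association survives Bonferroni correction across the non-candidate
#' family (per covariate): `p < family_alpha / m`.
#'
#' @param non_candidates analyte IDs outside the reference-prioritized set.
#' @param hv_assoc HV association table from [fit_cohort_regressions()].
#' @param family_alpha family-wise level (default 0.05).
#' @return data.frame with `bonferroni_p` (`min(1, m p)`) and `selected`.
#' @export
screen_tier2 <- function(non_candidates, hv_assoc, family_alpha = 0.05) {
  if (!length(non_candidates)) {
    return(data.frame(analyte_id = character(0), covariate = character(0),
                      hv_coefficient = numeric(0), hv_p = numeric(0),
                      bonferroni_p = numeric(0), selected = logical(0)))
  }
  out <- list()
  for (cv in c("age", "sex")) {
    hv <- assoc_lookup(hv_assoc, cv)
    fam <- intersect(non_candidates, rownames(hv))
    if (!length(fam)) next
    hv <- hv[fam, ]
    m <- length(fam)
    bonf <- pmin(1, m * hv$p_value)
    out[[cv]] <- data.frame(
      analyte_id = fam, covariate = cv,
      hv_coefficient = hv$coefficient, hv_p = hv$p_value,
      bonferroni_p = bonf, selected = bonf < family_alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build per-analyte HV adjustment models
#'
#' For every analyte selected by either tier, refits the joint HV regression
#' `log RFU ~ age + I(female)` and stores the coefficients together with the
#' HV anchor point (mean age, mean sex indicator). Analytes selected for both
#' covariates are adjusted for both from the single joint fit, avoiding
#' double-counting of shared variance.
#'
#' @param panel samples x analytes log-RFU matrix.
#' @param metadata aligned metadata.
#' @param tier1,tier2 screen tables from [screen_tier1()] / [screen_tier2()].
#' @return data.frame, one row per adjusted analyte.
#' @export
build_adjustment_models <- function(panel, metadata, tier1, tier2 = NULL) {
  sel <- rbind(
    if (!is.null(tier1) && nrow(tier1))
      data.frame(analyte_id = tier1$analyte_id[tier1$selected],
                 covariate = tier1$covariate[tier1$selected],
                 tier = rep(1L, sum(tier1$selected))),
    if (!is.null(tier2) && nrow(tier2))
      data.frame(analyte_id = tier2$analyte_id[tier2$selected],
                 covariate = tier2$covariate[tier2$selected],
                 tier = rep(2L, sum(tier2$selected))))
  if (is.null(sel) || !nrow(sel)) {
    return(data.frame(analyte_id = character(0)))
  }
  keep <- metadata$cohort == "HV"
  age <- metadata$age[keep]
  sex_f <- metadata$sex_f[keep]
  ids <- unique(sel$analyte_id)
  absent <- setdiff(ids, colnames(panel))
  if (length(absent)) stop("no panel column for selected analytes: ",
                           paste(absent, collapse = ", "))
  X <- cbind(1, age, sex_f)
  coefs <- qr.coef(qr(X), panel[keep, ids, drop = FALSE])
  conc <- rep(NA, length(ids))
  if (!is.null(tier1) && nrow(tier1)) {
    m <- match(ids, tier1$analyte_id)
    conc <- tier1$ms_concordant_with_hv[m]
  }
  data.frame(
    analyte_id = ids,
    adjust_age = vapply(ids, function(a)
      any(sel$covariate[sel$analyte_id == a] == "age"), logical(1)),
    adjust_sex = vapply(ids, function(a)
      any(sel$covariate[sel$analyte_id == a] == "sex"), logical(1)),
    hv_intercept = unname(coefs[1, ]),
    hv_age_slope = unname(coefs[2, ]),
    hv_sex_effect = unname(coefs[3, ]),
    hv_mean_age = mean(age),
    hv_mean_sexf = mean(sex_f),
    tier = vapply(ids, function(a) min(sel$tier[sel$analyte_id == a]),
                  integer(1)),
    ms_concordant_with_hv = conc,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Subtract HV-derived physiological age/sex effects from a panel
#'
#' For every modeled analyte and every sample (HV and MS alike):
#' `adjusted = observed - hv_age_slope * (age - hv_mean_age) -
#' hv_sex_effect * (sex_f - hv_mean_sexf)`, applying only the covariates the
#' analyte was selected for. Values stay on the log-RFU scale anchored at the
#' HV mean; unmodeled analytes pass through bit-identical.
#'
#' @param panel samples x analytes log-RFU matrix.
#' @param metadata aligned metadata.
#' @param models model table from [build_adjustment_models()].
#' @return Adjusted panel matrix of the same shape.
#' @export
adjust_panel <- function(panel, metadata, models) {
  stopifnot(nrow(panel) == nrow(metadata))
  if (!nrow(models)) return(panel)
  absent <- setdiff(models$analyte_id, colnames(panel))
  if (length(absent)) stop("adjustment model refers to absent analytes: ",
                           paste(absent, collapse = ", "))
  out <- panel
  for (i in seq_len(nrow(models))) {
    a <- models$analyte_id[i]
    corr <- 0
    if (models$adjust_age[i]) {
      corr <- corr + models$hv_age_slope[i] * (metadata$age - models$hv_mean_age[i])
    }
    if (models$adjust_sex[i]) {
      corr <- corr + models$hv_sex_effect[i] * (metadata$sex_f - models$hv_mean_sexf[i])
    }
    out[, a] <- panel[, a] - corr
  }
  out
}
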