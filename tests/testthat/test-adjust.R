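test_that("cohort regressions recover planted coefficients (OLS oracle)", {
  fx <- hv_fixture(n = 40, p = 3, seed = 1)
  fx$panel[, 1] <- 5 + 0.02 * fx$metadata$age + rnorm(40, 0, 1e-9)
  fx$panel[, 2] <- 8 + 1.0 * fx$metadata$sex_f + rnorm(40, 0, 1e-9)
  assoc <- fit_cohort_regressions(fx$panel, fx$metadata, "HV")
  a1 <- assoc[assoc$analyte_id == "APT0001" & assoc$covariate == "age", ]
  expect_lt(abs(a1$coefficient - 0.02), 1e-6)
  s1 <- assoc[assoc$analyte_id == "APT0001" & assoc$covariate == "sex", ]
  expect_lt(abs(s1$coefficient), 1e-6)
  s2 <- assoc[assoc$analyte_id == "APT0002" & assoc$covariate == "sex", ]
  expect_lt(abs(s2$coefficient - 1.0), 1e-6)
  expect_equal(s2$direction, 1)
  # coefficients and p-values agree with lm() on a per-analyte basis
  fit <- summary(lm(fx$panel[, 3] ~ age + sex_f, data = fx$metadata))
  a3 <- assoc[assoc$analyte_id == "APT0003", ]
  expect_equal(a3$coefficient, unname(fit$coefficients[2:3, 1]),
               tolerance = 1e-12)
  expect_equal(a3$p_value, unname(fit$coefficients[2:3, 4]),
               tolerance = 1e-12)
})

test_that("null analytes give uniform age p-values", {
  fx <- hv_fixture(n = 30, p = 1000, seed = 42)
  assoc <- fit_cohort_regressions(fx$panel, fx$metadata, "HV")
  p_age <- assoc$p_value[assoc$covariate == "age"]
  expect_gt(ks.test(p_age, "punif")$p.value, 0.01)
})

test_that("constant covariates are rejected by name", {
  fx <- hv_fixture(n = 10, p = 2)
  fx$metadata$sex <- "F"
  fx$metadata$sex_f <- 1
  expect_error(fit_cohort_regressions(fx$panel, fx$metadata, "HV"), "sex")
})

test_that("tier-1 screen applies the reference-concordance and MS rules", {
  ref <- data.frame(analyte_id = c("A", "B", "C"), covariate = "age",
                    coefficient = c(0.01, 0.01, 0.01), significant = TRUE)
  mk_assoc <- function(coefs, ps) {
    data.frame(analyte_id = c("A", "B", "C"), covariate = "age",
               cohort = "X", coefficient = coefs, se = 1, t = 1,
               p_value = ps, direction = sign(coefs))
  }
  # A: concordant with reference and MS-significant -> selected, concordant
  # B: HV direction opposes the reference -> rejected
  # C: selected but MS slope flips sign vs HV -> flagged discordant
  hv <- mk_assoc(c(0.02, -0.02, 0.02), c(0.001, 0.001, 0.01))
  ms <- mk_assoc(c(0.02, 0.02, -0.02), c(0.001, 0.001, 0.001))
  out <- screen_tier1(ref, hv, ms, alpha = 0.05)
  expect_true(out$selected[out$analyte_id == "A"])
  expect_true(out$ms_concordant_with_hv[out$analyte_id == "A"])
  expect_false(out$selected[out$analyte_id == "B"])
  expect_true(out$selected[out$analyte_id == "C"])
  expect_false(out$ms_concordant_with_hv[out$analyte_id == "C"])
})

test_that("tier-2 Bonferroni equals the min(1, m p) oracle", {
  set.seed(9)
  m <- 200
  ids <- sprintf("N%03d", 1:m)
  hv <- data.frame(analyte_id = rep(ids, 2),
                   covariate = rep(c("age", "sex"), each = m),
                   cohort = "HV", coefficient = rnorm(2 * m), se = 1, t = 1,
                   p_value = runif(2 * m), direction = 1)
  out <- screen_tier2(ids, hv, family_alpha = 0.05)
  for (cv in c("age", "sex")) {
    sub <- out[out$covariate == cv, ]
    p <- hv$p_value[hv$covariate == cv][match(sub$analyte_id, ids)]
    expect_equal(sub$bonferroni_p, pmin(1, m * p), tolerance = 1e-12)
    expect_identical(sub$selected, pmin(1, m * p) < 0.05)
  }
  expect_equal(nrow(screen_tier2(character(0), hv)), 0)
})

test_that("adjustment subtracts the HV-anchored covariate component", {
  models <- data.frame(analyte_id = "APT0001", adjust_age = TRUE,
                       adjust_sex = FALSE, hv_intercept = 7,
                       hv_age_slope = 0.02, hv_sex_effect = 0,
                       hv_mean_age = 40, hv_mean_sexf = 0.5, tier = 1L,
                       ms_concordant_with_hv = TRUE)
  panel <- matrix(c(7.0, 7.0), 2, 1,
                  dimnames = list(c("S1", "S2"), "APT0001"))
  md <- data.frame(sample_id = c("S1", "S2"), age = c(60, 40),
                   sex_f = c(0.5, 0.5))
  adj <- adjust_panel(panel, md, models)
  expect_equal(adj["S1", 1], 6.6)       # 7.0 - 0.02 * (60 - 40)
  expect_equal(adj["S2", 1], 7.0)       # at the HV anchor: unchanged
})

test_that("adjusted HV slopes vanish, re-adjustment is idempotent, and
           unselected analytes pass through bit-identically", {
  cfg <- simulation_config(n_hv = 24, n_ms = c(20, 20, 20), n_analytes = 20,
                           n_age_concordant = 4, n_age_discordant = 2,
                           n_sex = 2, n_tier2_age = 0, n_ms_excess = 1,
                           module_sizes = integer(0), residual_sd = 1e-9,
                           severity_noise_sd = 1, seed = 31)
  sim <- simulate_cohort(cfg)
  hv <- fit_cohort_regressions(sim$panel, sim$metadata, "HV")
  ms <- fit_cohort_regressions(sim$panel, sim$metadata, "MS")
  t1 <- screen_tier1(sim$reference, hv, ms)
  models <- build_adjustment_models(sim$panel, sim$metadata, t1)
  adj <- adjust_panel(sim$panel, sim$metadata, models)

  refit <- fit_cohort_regressions(adj, sim$metadata, "HV")
  for (i in seq_len(nrow(models))) {
    cv <- if (models$adjust_age[i]) "age" else "sex"
    got <- refit$coefficient[refit$analyte_id == models$analyte_id[i] &
                               refit$covariate == cv]
    expect_lt(abs(got), 1e-10)
  }

  hv2 <- fit_cohort_regressions(adj, sim$metadata, "HV")
  ms2 <- fit_cohort_regressions(adj, sim$metadata, "MS")
  t1b <- screen_tier1(sim$reference, hv2, ms2)
  models2 <- build_adjustment_models(adj, sim$metadata, t1b)
  adj2 <- adjust_panel(adj, sim$metadata, models2)
  expect_lt(max(abs(adj2 - adj)), 1e-8)

  untouched <- setdiff(colnames(sim$panel), models$analyte_id)
  expect_identical(adj[, untouched], sim$panel[, untouched])

  # the planted MS-excess age slope survives the physiological adjustment
  tr <- sim$truth$analytes
  excess_id <- tr$analyte_id[tr$class == "age_concordant" &
                               tr$ms_age_slope - tr$hv_age_slope > 0.01]
  ms_refit <- fit_cohort_regressions(adj, sim$metadata, "MS")
  got <- ms_refit[ms_refit$analyte_id == excess_id &
                    ms_refit$covariate == "age", ]
  expect_lt(abs(got$coefficient - 0.02), 1e-6)
  expect_lt(got$p_value, 1e-6)
})
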