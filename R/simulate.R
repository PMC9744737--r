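#' Simulation configuration for synthetic CSF cohorts
#'
#' Describes a synthetic study: a small healthy-volunteer (HV) cohort plus an
#' MS cohort split into RRMS/SPMS/PPMS subtypes, measured on an analyte panel
#' in natural-log RFU. Analytes fall into planted classes:
#'
#' * *age-concordant*: same log-linear age slope in HV and MS, present in the
#'   external serum reference;
#' * *age-discordant*: negative slope in HV, positive in MS (a disease-related
#'   process masquerading as aging), present in the reference;
#' * *sex-associated*: additive female/male shift, present in the reference;
#' * *tier-2 age*: age-associated in CSF but absent from the serum reference
#'   (only discoverable by the Bonferroni tier);
#' * *severity modules*: disjoint sets of analytes sharing a module factor;
#'   the latent severity is a weighted sum of their values plus noise;
#' * the remainder is pure noise.
#'
#' The first `n_ms_excess` concordant analytes additionally carry an extra
#' MS-only age slope (an MS process superimposed on physiological aging).
#'
#' @param n_hv HV cohort size.
#' @param n_ms MS cohort sizes, named `rrms`, `spms`, `ppms`.
#' @param n_analytes panel width.
#' @param n_age_concordant,n_age_discordant,n_sex,n_tier2_age,n_ms_excess
#'   planted class sizes (see Details).
#' @param module_sizes integer vector of severity-module sizes (disjoint from
#'   the age/sex classes).
#' @param age_slope HV (= MS) age slope for concordant analytes, log-RFU per
#'   year; signs alternate across analytes.
#' @param discordant_hv_slope,discordant_ms_slope slopes for discordant
#'   analytes in HV and MS.
#' @param sex_effect female-minus-male log-RFU shift; signs alternate.
#' @param ms_excess_slope extra MS age slope on the MS-excess analytes.
#' @param residual_sd per-analyte residual SD on the log scale.
#' @param module_loading loading of module members on their module factor.
#' @param module_weight severity weight of each module member.
#' @param target_marker_rho calibration target: the population Spearman-scale
#'   correlation between the strongest single module analyte and the latent
#'   severity; the severity noise SD is solved from it unless
#'   `severity_noise_sd` is given.
#' @param severity_noise_sd optional explicit severity noise SD (overrides
#'   `target_marker_rho`).
#' @param hv_age_range HV ages are uniform on this range.
#' @param ms_age_mean,ms_age_sd per-subtype normal age parameters
#'   (truncated to 18--75).
#' @param p_female probability of female sex.
#' @param proteomic_age_offset per-subtype shift (years) of the *biological*
#'   age driving the analytes, leaving chronological age untouched; used to
#'   plant aging-clock offsets.
#' @param bpfr_intercept,bpfr_age_slope linear trend of 1 - BPFr on age.
#' @param bpfr_deficit_sd SD of the per-subject brain-volume deficit.
#' @param bpfr_noise_sd measurement noise SD on 1 - BPFr.
#' @param deficit_severity_cor correlation between the planted deficit and
#'   the latent severity in MS subjects.
#' @param followup_noise_sd noise added to the follow-up severity outcome.
#' @param slope_noise_sd noise added to the synthetic progression slope.
#' @param n_ref_decoys number of pure-noise analytes nonetheless flagged
#'   significant in the serum reference (serum associations that do not
#'   replicate in CSF; they exercise the screen's false-positive control).
#' @param n_patient_clusters if > 0, MS subjects are assigned to this many
#'   planted clusters whose module-factor means are shifted by
#'   `patient_cluster_shift` with cluster-specific sign patterns.
#' @param patient_cluster_shift size of the module-factor mean shift.
#' @param seed RNG seed for this cohort draw.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_hv = 24,
                              n_ms = c(rrms = 37, spms = 31, ppms = 61),
                              n_analytes = 60,
                              n_age_concordant = 10,
                              n_age_discordant = 4,
                              n_sex = 6,
                              n_tier2_age = 2,
                              n_ms_excess = 1,
                              module_sizes = c(3, 3, 3, 3),
                              age_slope = 0.02,
                              discordant_hv_slope = -0.02,
                              discordant_ms_slope = 0.02,
                              sex_effect = 0.5,
                              ms_excess_slope = 0.02,
                              residual_sd = 0.25,
                              module_loading = 0.3,
                              module_weight = 1,
                              target_marker_rho = 0.35,
                              severity_noise_sd = NULL,
                              hv_age_range = c(20, 70),
                              ms_age_mean = c(rrms = 40.9, spms = 52.3, ppms = 54.8),
                              ms_age_sd = c(rrms = 11.1, spms = 9.0, ppms = 7.9),
                              p_female = 0.5,
                              proteomic_age_offset = c(rrms = 0, spms = 0, ppms = 0),
                              bpfr_intercept = 0.10,
                              bpfr_age_slope = 0.0015,
                              bpfr_deficit_sd = 0.02,
                              bpfr_noise_sd = 0.01,
                              deficit_severity_cor = 0.6,
                              followup_noise_sd = 0.3,
                              slope_noise_sd = 1,
                              n_ref_decoys = 6,
                              n_patient_clusters = 0,
                              patient_cluster_shift = 2,
                              seed = 1L) {
  n_ms <- stats::setNames(as.integer(n_ms), c("rrms", "spms", "ppms"))
  n_class <- n_age_concordant + n_age_discordant + n_sex + n_tier2_age +
    sum(module_sizes) + n_ref_decoys
  if (n_class > n_analytes) {
    stop("planted analyte classes (", n_class,
         ") exceed n_analytes (", n_analytes, ")")
  }
  if (n_ms_excess > n_age_concordant) {
    stop("n_ms_excess cannot exceed n_age_concordant")
  }
  stopifnot(n_hv >= 2, all(n_ms >= 2), residual_sd > 0,
            all(module_sizes >= 1) || length(module_sizes) == 0,
            bpfr_deficit_sd >= 0, bpfr_noise_sd >= 0,
            abs(deficit_severity_cor) <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# Population SD of the latent-severity noise that calibrates the strongest
# single module analyte to correlation `rho` with the latent severity.
# Module member j (module size m, loading lambda, residual sd sigma, weight w):
#   Var(x_j)      = lambda^2 + sigma^2
#   Cov(x_j, sig) = w (m lambda^2 + sigma^2)
#   Var(sig)      = sum_m w^2 (m^2 lambda^2 + m sigma^2)
# and rho = Cov / sqrt(Var(x) (Var(sig) + sd_noise^2)).
solve_severity_noise <- function(module_sizes, lambda, sigma, w, rho) {
  if (length(module_sizes) == 0) return(1)
  vx <- lambda^2 + sigma^2
  vs <- sum(w^2 * (module_sizes^2 * lambda^2 + module_sizes * sigma^2))
  m_max <- max(module_sizes)
  cv <- w * (m_max * lambda^2 + sigma^2)
  s2 <- cv^2 / (rho^2 * vx) - vs
  if (s2 <= 0) {
    warning("planted module structure already caps the single-marker ",
            "correlation below target_marker_rho; using noise SD 0")
    s2 <- 0
  }
  sqrt(s2)
}

# Per-analyte planted truth shared between training- and validation-like
# cohorts (reuse via the `truth` argument of simulate_cohort).
build_analyte_truth <- function(cfg) {
  p <- cfg$n_analytes
  id <- sprintf("APT%04d", seq_len(p))
  cls <- rep("noise", p)
  i <- 0
  take <- function(n) {
    out <- if (n > 0) (i + 1):(i + n) else integer(0)
    i <<- i + n
    out
  }
  idx_conc <- take(cfg$n_age_concordant); cls[idx_conc] <- "age_concordant"
  idx_disc <- take(cfg$n_age_discordant); cls[idx_disc] <- "age_discordant"
  idx_sex <- take(cfg$n_sex); cls[idx_sex] <- "sex"
  idx_t2 <- take(cfg$n_tier2_age); cls[idx_t2] <- "tier2_age"
  idx_decoy <- take(cfg$n_ref_decoys); cls[idx_decoy] <- "ref_decoy"
  module_id <- rep(NA_integer_, p)
  for (m in seq_along(cfg$module_sizes)) {
    idx <- take(cfg$module_sizes[m])
    cls[idx] <- "module"
    module_id[idx] <- m
  }
  alt <- function(idx) if (length(idx)) rep_len(c(1, -1), length(idx)) else numeric(0)
  hv_age_slope <- ms_age_slope <- sex_eff <- rep(0, p)
  hv_age_slope[idx_conc] <- cfg$age_slope * alt(idx_conc)
  ms_age_slope[idx_conc] <- hv_age_slope[idx_conc]
  if (cfg$n_ms_excess > 0) {
    excess <- idx_conc[seq_len(cfg$n_ms_excess)]
    ms_age_slope[excess] <- ms_age_slope[excess] + cfg$ms_excess_slope
  }
  hv_age_slope[idx_disc] <- cfg$discordant_hv_slope
  ms_age_slope[idx_disc] <- cfg$discordant_ms_slope
  sex_eff[idx_sex] <- cfg$sex_effect * alt(idx_sex)
  hv_age_slope[idx_t2] <- cfg$age_slope * alt(idx_t2)
  ms_age_slope[idx_t2] <- hv_age_slope[idx_t2]
  severity_weight <- ifelse(cls == "module", cfg$module_weight, 0)
  noise_sd <- if (is.null(cfg$severity_noise_sd)) {
    solve_severity_noise(cfg$module_sizes, cfg$module_loading,
                         cfg$residual_sd, cfg$module_weight,
                         cfg$target_marker_rho)
  } else cfg$severity_noise_sd
  list(
    analytes = data.frame(
      analyte_id = id, class = cls,
      in_reference = cls %in% c("age_concordant", "age_discordant", "sex",
                                "ref_decoy"),
      hv_age_slope = hv_age_slope, ms_age_slope = ms_age_slope,
      sex_effect = sex_eff, module_id = module_id,
      severity_weight = severity_weight,
      intercept = stats::rnorm(p, mean = 8, sd = 1),
      stringsAsFactors = FALSE),
    severity_noise_sd = noise_sd,
    module_loading = cfg$module_loading,
    residual_sd = cfg$residual_sd
  )
}

#' Simulate a CSF proteomic cohort with planted ground truth
#'
#' Draws one HV + MS cohort under a [simulation_config()]. Analyte values are
#' `intercept + slope_age * (biological age - 45) + sex_effect * I(female) +
#' loading * module_factor + noise` on the natural-log RFU scale; the latent
#' MS severity is the weighted sum of centred module-analyte values plus
#' noise, and severity outcomes (`msdss_baseline`, `msdss_followup`,
#' `progression_slope`, `armss`) and BPFr derive from it.
#'
#' To draw an independent validation cohort sharing the same planted analyte
#' effects, pass the `truth` element of a previous call (and a different
#' `seed` in `config`).
#'
#' @param config a [simulation_config()].
#' @param truth optional analyte-level truth from a previous call.
#' @return list with `panel` (log-RFU matrix), `metadata`, `reference`
#'   (external serum coefficient table) and `truth` (analyte table, subject
#'   table with `latent_severity`, `true_deficit`, `patient_cluster`, and the
#'   calibrated severity noise SD).
#' @export
simulate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (is.null(truth)) truth <- build_analyte_truth(config)
  an <- truth$analytes
  p <- nrow(an)
  n_ms <- sum(config$n_ms)
  n <- config$n_hv + n_ms
  subtype <- c(rep("HV", config$n_hv),
               rep(c("RRMS", "SPMS", "PPMS"), config$n_ms))
  cohort <- ifelse(subtype == "HV", "HV", "MS")
  subject_id <- c(sprintf("HV%03d", seq_len(config$n_hv)),
                  sprintf("MS%03d", seq_len(n_ms)))
  age <- numeric(n)
  age[cohort == "HV"] <- stats::runif(config$n_hv, config$hv_age_range[1],
                                      config$hv_age_range[2])
  for (st in c("rrms", "spms", "ppms")) {
    idx <- subtype == toupper(st)
    age[idx] <- pmin(75, pmax(18, stats::rnorm(sum(idx), config$ms_age_mean[[st]],
                                               config$ms_age_sd[[st]])))
  }
  sex_f <- stats::rbinom(n, 1, config$p_female)
  offset <- rep(0, n)
  for (st in c("rrms", "spms", "ppms")) {
    offset[subtype == toupper(st)] <- config$proteomic_age_offset[[st]]
  }
  bio_age <- age + offset

  n_mod <- length(config$module_sizes)
  factors <- matrix(stats::rnorm(n * max(1, n_mod)), n, max(1, n_mod))
  patient_cluster <- rep(NA_integer_, n)
  if (config$n_patient_clusters > 0 && n_mod > 0) {
    K <- config$n_patient_clusters
    ms_idx <- which(cohort == "MS")
    patient_cluster[ms_idx] <- sample(rep_len(seq_len(K), length(ms_idx)))
    # cluster sign patterns over modules: codes spread across {0 .. 2^M - 1}
    # so distinct clusters differ in as many modules as possible
    codes <- round(seq(0, 2^n_mod - 1, length.out = K))
    signs <- function(m, c) {
      if (bitwAnd(codes[c], bitwShiftL(1L, m - 1L)) > 0) 1 else -1
    }
    for (i in ms_idx) {
      for (m in seq_len(n_mod)) {
        factors[i, m] <- factors[i, m] +
          config$patient_cluster_shift * signs(m, patient_cluster[i])
      }
    }
  }

  panel <- matrix(0, n, p, dimnames = list(paste0(subject_id, "_v1"),
                                           an$analyte_id))
  is_ms <- cohort == "MS"
  for (j in seq_len(p)) {
    slope <- ifelse(is_ms, an$ms_age_slope[j], an$hv_age_slope[j])
    mu <- an$intercept[j] + slope * (bio_age - 45) + an$sex_effect[j] * sex_f
    if (!is.na(an$module_id[j])) {
      mu <- mu + truth$module_loading * factors[, an$module_id[j]]
    }
    panel[, j] <- mu + stats::rnorm(n, 0, truth$residual_sd)
  }

  mod_cols <- which(!is.na(an$module_id))
  signal <- if (length(mod_cols)) {
    as.vector((panel[, mod_cols, drop = FALSE] -
                 matrix(an$intercept[mod_cols], n, length(mod_cols),
                        byrow = TRUE)) %*% an$severity_weight[mod_cols])
  } else rep(0, n)
  latent <- signal + stats::rnorm(n, 0, truth$severity_noise_sd)
  latent[!is_ms] <- NA_real_

  bv <- simulate_brain_volume(age, latent,
                              intercept = config$bpfr_intercept,
                              age_slope = config$bpfr_age_slope,
                              deficit_sd = config$bpfr_deficit_sd,
                              noise_sd = config$bpfr_noise_sd,
                              severity_cor = config$deficit_severity_cor)

  metadata <- data.frame(
    sample_id = rownames(panel), subject_id = subject_id, cohort = cohort,
    subtype = subtype, age = age, sex = ifelse(sex_f == 1, "F", "M"),
    sex_f = sex_f, visit_index = 1L,
    msdss_baseline = latent,
    msdss_followup = latent + ifelse(is_ms, stats::rnorm(n, 0, config$followup_noise_sd), NA),
    progression_slope = latent + ifelse(is_ms, stats::rnorm(n, 0, config$slope_noise_sd), NA),
    armss = latent + ifelse(is_ms, stats::rnorm(n, 0, config$slope_noise_sd), NA),
    bpfr = bv$bpfr,
    stringsAsFactors = FALSE)

  ref <- an[an$in_reference, , drop = FALSE]
  covariate <- ifelse(ref$class == "sex", "sex", "age")
  coefficient <- 0.7 * ifelse(ref$class == "sex", ref$sex_effect,
                              ref$hv_age_slope)
  # decoys: serum-significant but no CSF effect; alternate covariate and sign
  dec <- which(ref$class == "ref_decoy")
  if (length(dec)) {
    covariate[dec] <- rep_len(c("age", "sex"), length(dec))
    coefficient[dec] <- rep_len(c(0.014, -0.35, -0.014, 0.35), length(dec))
  }
  reference <- data.frame(
    analyte_id = ref$analyte_id, covariate = covariate,
    coefficient = coefficient,
    significant = rep(TRUE, nrow(ref)), stringsAsFactors = FALSE)
  reference$direction <- sign(reference$coefficient)

  truth$subjects <- data.frame(
    sample_id = rownames(panel), latent_severity = latent,
    true_deficit = bv$true_deficit, patient_cluster = patient_cluster,
    biological_age = bio_age, stringsAsFactors = FALSE)
  list(panel = panel, metadata = metadata, reference = reference, truth = truth)
}

#' Simulate brain parenchymal fraction with an age trend and planted deficit
#'
#' Generates `1 - BPFr = intercept + age_slope * age + deficit + noise`, where
#' the per-subject deficit is correlated (`severity_cor`) with a supplied
#' standardized severity where available and independent noise otherwise.
#'
#' @param age numeric vector of ages.
#' @param severity latent severity (NA for samples without one, e.g. HV).
#' @param intercept,age_slope linear trend of 1 - BPFr on age
#'   (`age_slope > 0`: older brains have lower parenchymal fraction).
#' @param deficit_sd,noise_sd SDs of the planted deficit and of measurement
#'   noise.
#' @param severity_cor correlation of the deficit with severity.
#' @return list with `bpfr` and `true_deficit` vectors.
#' @export
simulate_brain_volume <- function(age, severity = NULL,
                                  intercept = 0.10, age_slope = 0.0015,
                                  deficit_sd = 0.02, noise_sd = 0.01,
                                  severity_cor = 0.6) {
  stopifnot(age_slope > 0)
  n <- length(age)
  z_sev <- rep(0, n)
  r <- rep(0, n)
  if (!is.null(severity) && any(!is.na(severity))) {
    ok <- !is.na(severity)
    z_sev[ok] <- as.vector(scale(severity[ok]))
    r[ok] <- severity_cor
  }
  deficit <- deficit_sd * (r * z_sev + sqrt(1 - r^2) * stats::rnorm(n))
  one_minus <- intercept + age_slope * age + deficit +
    stats::rnorm(n, 0, noise_sd)
  list(bpfr = 1 - one_minus, true_deficit = deficit)
}

#' Simulate longitudinal severity measurements
#'
#' Draws `severity_ij = mu + b_i + e_ij` with subject random intercepts
#' `b_i ~ N(0, var_between)` and visit noise `e_ij ~ N(0, var_within)`, so
#' the population one-way intraclass correlation is
#' `var_between / (var_between + var_within)`.
#'
#' @param n_subjects number of subjects.
#' @param k visits per subject (>= 2).
#' @param mu grand mean.
#' @param var_between,var_within variance components. The defaults give a
#'   population ICC of 0.90, the stability regime of a severity scale whose
#'   repeated measurements are nearly interchangeable within a patient.
#' @param seed optional RNG seed.
#' @return Long data.frame with `subject_id`, `visit_index`, `severity`.
#' @export
simulate_longitudinal_severity <- function(n_subjects = 500, k = 5, mu = 2,
                                           var_between = 9, var_within = 1,
                                           seed = NULL) {
  if (k < 2) stop("at least 2 visits per subject are required")
  stopifnot(n_subjects >= 2, var_between >= 0, var_within >= 0)
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n_subjects, 0, sqrt(var_between))
  data.frame(
    subject_id = rep(sprintf("S%04d", seq_len(n_subjects)), each = k),
    visit_index = rep(seq_len(k), n_subjects),
    severity = mu + rep(b, each = k) +
      stats::rnorm(n_subjects * k, 0, sqrt(var_within)))
}
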