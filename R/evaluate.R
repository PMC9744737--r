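#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurements about the identity line:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, using population
#' (divide-by-n) moments as in Lin's original estimator; sample (n-1)
#' moments are available by flag.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param population use divide-by-n moments (default TRUE).
#' @return CCC in `[-1, 1]`; NaN with a warning when either input is
#'   constant.
#' @export
concordance_ccc <- function(x, y, population = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  n <- length(x)
  f <- if (population) (n - 1) / n else 1
  sx <- stats::var(x) * f
  sy <- stats::var(y) * f
  sxy <- stats::cov(x, y) * f
  if (sx == 0 || sy == 0) {
    warning("constant input; CCC undefined")
    return(NaN)
  }
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}

#' Evaluate predicted vs observed severity
#'
#' The evaluation triple used for both training and independent-cohort
#' validation: Spearman rho with its two-sided p-value, R-squared as the
#' squared Pearson correlation of the observed-predicted fit, and Lin's CCC.
#'
#' @param observed,predicted paired numeric vectors, n >= 4, no NAs.
#' @param cohort optional label (`"training"` / `"validation"`).
#' @return list with `cohort`, `n`, `spearman_rho`, `spearman_p`,
#'   `r_squared`, `ccc`.
#' @export
evaluate_predictions <- function(observed, predicted, cohort = NA_character_) {
  stopifnot(length(observed) == length(predicted))
  if (anyNA(observed) || anyNA(predicted)) stop("missing values in input")
  if (length(observed) < 4) stop("need at least 4 paired observations")
  ct <- suppressWarnings(stats::cor.test(observed, predicted,
                                         method = "spearman", exact = FALSE))
  r <- stats::cor(observed, predicted)
  list(cohort = cohort, n = length(observed),
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       r_squared = r^2, ccc = concordance_ccc(observed, predicted))
}

#' Correlate severity predictors with prospective progression slopes
#'
#' Spearman correlation of each supplied predictor column (CSF-model
#' predictions, clinical severity scales, NFL, ...) against a prospectively
#' measured progression slope, Benjamini-Hochberg adjusted across the
#' predictor family. Predictors with fewer than 4 paired values are skipped
#' with a warning.
#'
#' @param predictors data.frame of predictor columns.
#' @param slope numeric progression slope, aligned to `predictors` rows.
#' @return data.frame with `predictor`, `n`, `spearman_rho`, `p_value`,
#'   `fdr_q`.
#' @export
validate_progression <- function(predictors, slope) {
  stopifnot(nrow(predictors) == length(slope))
  rows <- list()
  for (nm in names(predictors)) {
    x <- predictors[[nm]]
    ok <- !is.na(x) & !is.na(slope)
    if (sum(ok) < 4) {
      warning("predictor '", nm, "' has fewer than 4 paired values; skipped")
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], slope[ok],
                                           method = "spearman", exact = FALSE))
    rows[[nm]] <- data.frame(predictor = nm, n = sum(ok),
                             spearman_rho = unname(ct$estimate),
                             p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no predictor had enough paired values")
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Cohort balance tests between training and validation cohorts
#'
#' Sex is compared with a 2x2 chi-square test (Yates continuity correction);
#' each quantitative variable with a two-sided Wilcoxon rank-sum test.
#'
#' @param metadata_train,metadata_valid metadata data.frames (need `sex`;
#'   quantitative columns are taken from `vars`).
#' @param vars quantitative columns to test (those present in both cohorts).
#' @return data.frame with `variable`, `test`, `statistic`, `p_value`.
#' @export
compare_cohorts <- function(metadata_train, metadata_valid,
                            vars = c("age", "disease_duration", "edss",
                                     "msdss_baseline")) {
  if (!nrow(metadata_train) || !nrow(metadata_valid)) {
    stop("both cohorts must be non-empty")
  }
  tab <- rbind(train = table(factor(metadata_train$sex, c("F", "M"))),
               valid = table(factor(metadata_valid$sex, c("F", "M"))))
  if (any(colSums(tab) == 0)) stop("a sex category is empty")
  chi <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  rows <- list(data.frame(variable = "sex", test = "chi-square (Yates)",
                          statistic = unname(chi$statistic),
                          p_value = chi$p.value, stringsAsFactors = FALSE))
  for (v in intersect(vars, intersect(names(metadata_train),
                                      names(metadata_valid)))) {
    x <- metadata_train[[v]]; y <- metadata_valid[[v]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) next
    w <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    rows[[v]] <- data.frame(variable = v, test = "Wilcoxon rank-sum",
                            statistic = unname(w$statistic),
                            p_value = w$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
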