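#' Brain-volume-deficit (BVD) severity
#'
#' Regresses `1 - BPFr` on age over the MS baseline cohort and returns the
#' residuals as the BVD severity outcome: positive values indicate more CNS
#' tissue loss than equally aged peers.
#'
#' @param bpfr brain parenchymal fraction, in (0, 1).
#' @param age ages, same length.
#' @param ms_baseline_mask logical mask of the MS baseline samples the
#'   regression is fitted on (one baseline row per subject).
#' @return list with `bvd_severity` (full-length vector, NA outside the
#'   mask), and the fitted `slope`, `t` and `p` of the age term.
#' @export
compute_bvd_severity <- function(bpfr, age, ms_baseline_mask) {
  stopifnot(length(bpfr) == length(age),
            length(ms_baseline_mask) == length(age))
  b <- bpfr[ms_baseline_mask]
  a <- age[ms_baseline_mask]
  if (any(!is.na(b) & (b <= 0 | b >= 1))) {
    stop("BPFr values must lie strictly inside (0, 1)")
  }
  if (stats::var(a) == 0) stop("age is constant in the BVD fitting cohort")
  fit <- stats::lm((1 - b) ~ a)
  # suppress the "essentially perfect fit" note on noiseless input
  sm <- suppressWarnings(summary(fit))$coefficients
  out <- rep(NA_real_, length(age))
  out[ms_baseline_mask] <- stats::residuals(fit)
  list(bvd_severity = out, slope = unname(sm["a", "Estimate"]),
       t = unname(sm["a", "t value"]), p = unname(sm["a", "Pr(>|t|)"]))
}

#' One-way random-effects intraclass correlation
#'
#' Quantifies intra-individual stability of repeated severity measurements:
#' the one-way ANOVA decomposition gives
#' `ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW)`, with the standard
#' unbalanced-design coefficient `k0 = (N - sum(k_i^2)/N) / (n_subjects - 1)`.
#' The estimate can be negative when the between-subject variance estimate is
#' non-positive; if all values are identical the result is NaN with a
#' warning.
#'
#' @param long_table data.frame with `subject_id` and `severity` columns
#'   (one row per visit).
#' @return list with `icc`, `msb`, `msw`, `k0`, `n_subjects`, `n_obs`.
#' @export
compute_icc <- function(long_table) {
  stopifnot(all(c("subject_id", "severity") %in% names(long_table)))
  y <- long_table$severity
  g <- factor(long_table$subject_id)
  k_i <- table(g)
  if (sum(k_i >= 2) < 2) {
    stop("ICC requires at least 2 subjects with at least 2 visits each")
  }
  n <- length(y)
  a <- nlevels(g)
  # only the mean squares are used; the F-test (and its perfect-fit
  # warning) is irrelevant here
  ms <- suppressWarnings(stats::anova(stats::lm(y ~ g)))[["Mean Sq"]]
  msb <- ms[1]
  msw <- ms[2]
  k0 <- (n - sum(k_i^2) / n) / (a - 1)
  if (stats::var(y) == 0) {
    warning("all severity values identical; ICC undefined")
    icc <- NaN
  } else {
    icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  }
  list(icc = icc, msb = msb, msw = msw, k0 = k0, n_subjects = a, n_obs = n)
}
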