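#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Monotone adjusted values (q-values), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Univariate Spearman screen of analytes against severity outcomes
#'
#' Computes, per analyte and outcome, the Spearman correlation with its
#' two-sided p-value, and Benjamini-Hochberg q-values within each outcome
#' family. Samples with a missing outcome are dropped pairwise.
#'
#' @param adjusted_panel samples x analytes matrix (HV age/sex-adjusted
#'   log RFU).
#' @param outcomes data.frame of outcome columns aligned to the panel rows.
#' @return data.frame with `analyte_id`, `outcome`, `n`, `spearman_rho`,
#'   `p_value`, `fdr_q`, `rank` (by increasing p within outcome).
#' @export
correlate_outcomes <- function(adjusted_panel, outcomes) {
  stopifnot(nrow(adjusted_panel) == nrow(outcomes))
  res <- list()
  for (oc in names(outcomes)) {
    y <- outcomes[[oc]]
    ok <- !is.na(y)
    if (sum(ok) < 4) stop("outcome '", oc, "' has fewer than 4 observations")
    if (stats::var(y[ok]) == 0) stop("outcome '", oc, "' is constant")
    yy <- y[ok]
    rho <- p <- numeric(ncol(adjusted_panel))
    for (j in seq_len(ncol(adjusted_panel))) {
      x <- adjusted_panel[ok, j]
      if (stats::var(x) == 0) {
        warning("analyte '", colnames(adjusted_panel)[j],
                "' is constant; correlation undefined")
        rho[j] <- NaN; p[j] <- NaN
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, yy, method = "spearman", exact = FALSE))
        rho[j] <- unname(ct$estimate)
        p[j] <- ct$p.value
      }
    }
    q <- rep(NaN, length(p))
    q[!is.nan(p)] <- bh_adjust(p[!is.nan(p)])
    res[[oc]] <- data.frame(
      analyte_id = colnames(adjusted_panel), outcome = oc, n = sum(ok),
      spearman_rho = rho, p_value = p, fdr_q = q,
      rank = rank(p, ties.method = "first", na.last = "keep"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export ranked analyte lists for external enrichment tools
#'
#' Per outcome, writes plain-text one-symbol-per-line lists: the full panel
#' ordered by decreasing `|rho|` and by increasing p-value, plus the
#' significant positive and negative sublists (`fdr_q < alpha`, split by
#' correlation sign). Intended as input to STRING / g:Profiler style web
#' services, whose enrichment statistics are outside this package.
#'
#' @param screen_results output of [correlate_outcomes()].
#' @param outdir directory for the list files.
#' @param mapping optional named character vector, analyte ID to gene symbol;
#'   unmapped analytes keep their aptamer ID with a warning.
#' @param alpha FDR threshold for the significant sublists.
#' @return Invisibly, the written file paths.
#' @export
rank_for_enrichment <- function(screen_results, outdir, mapping = NULL,
                                alpha = 0.05) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  symbol_of <- function(ids) {
    if (is.null(mapping)) return(stats::setNames(ids, ids))
    sym <- mapping[ids]
    if (anyNA(sym)) {
      warning("unmapped analytes kept under their aptamer IDs: ",
              paste(ids[is.na(sym)], collapse = ", "))
      sym[is.na(sym)] <- ids[is.na(sym)]
    }
    stats::setNames(unname(sym), ids)
  }
  files <- character(0)
  for (oc in unique(screen_results$outcome)) {
    d <- screen_results[screen_results$outcome == oc &
                          !is.nan(screen_results$p_value), , drop = FALSE]
    sym <- symbol_of(d$analyte_id)
    emit <- function(ids, tag) {
      f <- file.path(outdir, sprintf("ranked_%s_%s.txt", oc, tag))
      writeLines(unname(sym[ids]), f)
      files <<- c(files, f)
    }
    emit(d$analyte_id[order(-abs(d$spearman_rho), d$analyte_id)], "by_rho")
    emit(d$analyte_id[order(d$p_value, d$analyte_id)], "by_p")
    sig <- d[d$fdr_q < alpha, , drop = FALSE]
    emit(sig$analyte_id[sig$spearman_rho > 0][order(sig$p_value[sig$spearman_rho > 0])], "pos")
    emit(sig$analyte_id[sig$spearman_rho < 0][order(sig$p_value[sig$spearman_rho < 0])], "neg")
  }
  invisible(files)
}
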