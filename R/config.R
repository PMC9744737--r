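#' Pipeline configuration
#'
#' Bundles the file paths, statistical thresholds, random-forest parameters
#' and seed that drive a full analysis run. All analyte values are carried
#' internally as natural-log RFU; `log_transform = TRUE` means the panel file
#' holds raw RFU and the natural log is applied on load.
#'
#' @param panel_path,metadata_path,reference_path paths to the wide analyte
#'   panel, the sample metadata table and the external serum reference
#'   coefficient table (TSV or CSV; delimiter auto-detected).
#' @param log_transform logical; `TRUE` if the panel holds raw RFU that must
#'   be log-transformed on load, `FALSE` if values are already natural-log.
#' @param tier1_alpha per-test significance level for the reference-anchored
#'   tier-1 screen (HV significance and MS FDR-adjusted significance).
#' @param tier2_alpha family-wise (Bonferroni) level for the tier-2 screen of
#'   analytes absent from the serum reference.
#' @param n_forests_per_step number of random forests averaged per
#'   elimination step.
#' @param drop_fraction fraction of lowest-importance features removed per
#'   elimination step.
#' @param floor elimination stops once at most this many features remain.
#' @param ntree_selection trees per forest during backward elimination.
#' @param ntree_final trees in the final severity forest.
#' @param cut_rule `"1se"` (smallest feature count whose mean OOB error is
#'   within one SD of the global minimum) or `"min"` (global minimum).
#' @param k_modules,k_patients cluster counts for the heterogeneity stage.
#' @param seed master seed; every stochastic stage derives its own child
#'   seed from it via [derive_seed()].
#' @param outdir output directory for [write_results_bundle()].
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(panel_path = NULL,
                            metadata_path = NULL,
                            reference_path = NULL,
                            log_transform = FALSE,
                            tier1_alpha = 0.05,
                            tier2_alpha = 0.05,
                            n_forests_per_step = 10L,
                            drop_fraction = 0.10,
                            floor = 3L,
                            ntree_selection = 200L,
                            ntree_final = 40000L,
                            cut_rule = c("min", "1se"),
                            k_modules = 4L,
                            k_patients = 7L,
                            seed = 1L,
                            outdir = ".") {
  cut_rule <- match.arg(cut_rule)
  stopifnot(
    tier1_alpha > 0, tier1_alpha < 1,
    tier2_alpha > 0, tier2_alpha < 1,
    drop_fraction > 0, drop_fraction < 1,
    floor >= 1, n_forests_per_step >= 1,
    ntree_selection >= 1, ntree_final >= 1,
    k_modules >= 1, k_patients >= 1
  )
  structure(list(
    panel_path = panel_path, metadata_path = metadata_path,
    reference_path = reference_path, log_transform = log_transform,
    tier1_alpha = tier1_alpha, tier2_alpha = tier2_alpha,
    n_forests_per_step = as.integer(n_forests_per_step),
    drop_fraction = drop_fraction, floor = as.integer(floor),
    ntree_selection = as.integer(ntree_selection),
    ntree_final = as.integer(ntree_final),
    cut_rule = cut_rule,
    k_modules = as.integer(k_modules), k_patients = as.integer(k_patients),
    seed = as.integer(seed), outdir = outdir
  ), class = "pipeline_config")
}

#' Derive a reproducible child seed from a master seed
#'
#' Each stochastic stage of the pipeline owns a fixed stage index; its seed
#' is a deterministic function of (master seed, stage index), so any stage
#' can be re-run in isolation with the seed logged in the manifest. The
#' mapping is a multiplicative hash reduced modulo 2^31 - 1, keeping the
#' result a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 0).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, length(stage) == 1, stage >= 0)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(stage) * 16807 + 1
  as.integer(x %% (m - 1) + 1)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("CSF severity pipeline configuration\n")
  cat(sprintf("  tier-1 alpha %.3g, tier-2 family alpha %.3g\n",
              x$tier1_alpha, x$tier2_alpha))
  cat(sprintf("  elimination: %d forests/step, drop %.0f%%, floor %d, ntree %d (selection) / %d (final), cut rule '%s'\n",
              x$n_forests_per_step, 100 * x$drop_fraction, x$floor,
              x$ntree_selection, x$ntree_final, x$cut_rule))
  cat(sprintf("  clustering: %d protein modules x %d patient clusters\n",
              x$k_modules, x$k_patients))
  cat(sprintf("  master seed %d\n", x$seed))
  invisible(x)
}
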