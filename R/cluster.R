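#' Z-score a panel over the MS cohort
#'
#' Standardizes each selected analyte to mean 0 / SD 1 over the masked
#' samples; zero-SD analytes are dropped with a warning.
#'
#' @param adjusted_panel samples x analytes matrix (HV age/sex-adjusted).
#' @param selected_analytes analyte IDs to keep.
#' @param cohort_mask logical mask of the samples to standardize over
#'   (default all).
#' @return samples x analytes z-score matrix (masked samples only).
#' @export
zscore_matrix <- function(adjusted_panel, selected_analytes = colnames(adjusted_panel),
                          cohort_mask = rep(TRUE, nrow(adjusted_panel))) {
  if (sum(cohort_mask) < 2) stop("need at least 2 samples")
  absent <- setdiff(selected_analytes, colnames(adjusted_panel))
  if (length(absent)) stop("panel is missing analytes: ",
                           paste(absent, collapse = ", "))
  x <- adjusted_panel[cohort_mask, selected_analytes, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-SD analytes dropped: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(x)) stop("no analytes left after dropping zero-SD columns")
  scale(x, center = TRUE, scale = sds)
}

#' Two-way hierarchical clustering into patient clusters and protein modules
#'
#' Agglomerative clustering with Ward's minimum-variance linkage on
#' Euclidean distances, in the convention where input distances are squared
#' before the Lance-Williams update (`hclust` method `"ward.D2"`). The
#' sample (row) tree is cut at `k_patients` and the analyte (column) tree at
#' `k_modules`. Deterministic: identical input gives identical dendrograms;
#' equal merge costs are resolved by `hclust`'s lowest-index-first rule.
#'
#' @param z z-score matrix from [zscore_matrix()] (samples x analytes).
#' @param k_patients number of patient clusters (default 7).
#' @param k_modules number of protein modules (default 4).
#' @return list with `patient_cluster` (named integer vector),
#'   `protein_module` (named integer vector), and the two `hclust` trees.
#' @export
cluster_bimodal <- function(z, k_patients = 7, k_modules = 4) {
  if (k_patients > nrow(z)) stop("k_patients exceeds the number of samples")
  if (k_modules > ncol(z)) stop("k_modules exceeds the number of analytes")
  tree_p <- stats::hclust(stats::dist(z), method = "ward.D2")
  tree_m <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  list(patient_cluster = stats::cutree(tree_p, k = k_patients),
       protein_module = stats::cutree(tree_m, k = k_modules),
       patient_tree = tree_p, module_tree = tree_m)
}

#' Per-cluster composition summary
#'
#' Descriptive layer over the bimodal clustering: per patient cluster, the
#' sample count, subtype and sex counts, median severity outcomes, and the
#' mean z-score of each protein module.
#'
#' @param assignment output of [cluster_bimodal()].
#' @param metadata metadata rows for the clustered samples (matched by
#'   `sample_id`).
#' @param z the z-score matrix used for clustering.
#' @param outcome_cols outcome columns to summarize by median (those present
#'   and non-empty; empty ones are omitted with a warning).
#' @return data.frame, one row per patient cluster.
#' @export
summarize_clusters <- function(assignment, metadata, z,
                               outcome_cols = c("msdss_baseline", "bvd_severity")) {
  pc <- assignment$patient_cluster
  md <- metadata[match(names(pc), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata rows missing for clustered samples")
  keep_oc <- character(0)
  for (oc in outcome_cols) {
    if (!oc %in% names(md) || all(is.na(md[[oc]]))) {
      warning("outcome column '", oc, "' absent or empty; omitted")
    } else keep_oc <- c(keep_oc, oc)
  }
  rows <- lapply(sort(unique(pc)), function(cl) {
    idx <- pc == cl
    row <- data.frame(cluster = cl, n = sum(idx))
    for (st in c("RRMS", "SPMS", "PPMS")) {
      row[[paste0("n_", tolower(st))]] <- sum(md$subtype[idx] == st)
    }
    row$n_female <- sum(md$sex[idx] == "F")
    row$n_male <- sum(md$sex[idx] == "M")
    for (oc in keep_oc) {
      row[[paste0("median_", oc)]] <- stats::median(md[[oc]][idx], na.rm = TRUE)
    }
    for (m in sort(unique(assignment$protein_module))) {
      cols <- names(assignment$protein_module)[assignment$protein_module == m]
      row[[paste0("mean_z_module", m)]] <- mean(z[idx, cols, drop = FALSE])
    }
    row
  })
  do.call(rbind, rows)
}
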