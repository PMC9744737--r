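#' Expand an analyte panel into single + pairwise-ratio features
#'
#' Builds the candidate feature set for severity modeling: every analyte as
#' itself plus one ratio feature per unordered analyte pair. Because the
#' panel is on the natural-log scale, a ratio is stored as the log
#' difference; the orientation is deterministic (numerator = the
#' lexicographically smaller analyte ID), so `A/B = value(A) - value(B)` and
#' exactly one of each pair is emitted.
#'
#' @param panel samples x analytes log-RFU matrix; analyte IDs must be
#'   unique and must not contain `/`.
#' @return samples x features matrix; feature IDs are `A` or `A/B`.
#' @export
expand_ratios <- function(panel) {
  ids <- colnames(panel)
  if (anyDuplicated(ids)) stop("duplicate analyte IDs")
  if (any(grepl("/", ids, fixed = TRUE))) {
    stop("analyte IDs must not contain '/'")
  }
  ord <- order(ids)
  X <- panel[, ord, drop = FALSE]
  p <- ncol(X)
  if (p < 2) return(panel)
  pair <- utils::combn(p, 2)
  ratios <- X[, pair[1, ], drop = FALSE] - X[, pair[2, ], drop = FALSE]
  colnames(ratios) <- paste(colnames(X)[pair[1, ]], colnames(X)[pair[2, ]],
                            sep = "/")
  cbind(panel, ratios)
}

#' Number of features after ratio expansion
#' @param p number of analytes.
#' @return `p + p(p-1)/2`, computed without materializing the matrix.
#' @export
n_ratio_features <- function(p) p + p * (p - 1) / 2

#' Unique analytes contributing to a set of features
#' @param feature_ids character vector of `A` / `A/B` feature IDs.
#' @return Sorted unique analyte IDs.
#' @export
feature_analytes <- function(feature_ids) {
  sort(unique(unlist(strsplit(feature_ids, "/", fixed = TRUE))))
}

#' Backward-elimination feature-count schedule
#'
#' Deterministic iteration `p <- p - max(1, floor(drop_fraction * p))` from
#' the starting count down to the floor; the returned sequence includes both
#' endpoints. The `max(1, .)` guarantees progress below `1/drop_fraction`
#' features.
#'
#' @param p starting feature count.
#' @param drop_fraction fraction removed per step (default 0.10).
#' @param floor stopping count (default 3).
#' @return Integer vector of feature counts, strictly decreasing.
#' @export
elimination_schedule <- function(p, drop_fraction = 0.10, floor = 3) {
  stopifnot(p >= 1, floor >= 1)
  out <- p
  while (p > floor) {
    p <- p - max(1, base::floor(drop_fraction * p))
    out <- c(out, p)
  }
  out
}

#' Random-forest mtry rule
#'
#' `mtry = factor * sqrt(p)`, rounded half up and clipped to `[1, p]`.
#'
#' @param p number of available features.
#' @param factor multiplier on `sqrt(p)` (default 3).
#' @return Integer mtry.
#' @export
rf_mtry <- function(p, factor = 3) {
  as.integer(min(p, max(1, base::floor(factor * sqrt(p) + 0.5))))
}

#' Iterative random-forest feature elimination
#'
#' At each feature count of the [elimination_schedule()], fits
#' `n_forests_per_step` regression forests with distinct derived seeds,
#' records the mean and SD of their out-of-bag (OOB) mean squared errors,
#' averages their node-impurity (variance-reduction) importances, and drops
#' the `max(1, floor(drop_fraction * p))` lowest-importance features (ties
#' broken by feature ID). The cut point is chosen from the OOB trace:
#' `"1se"` takes the smallest feature count whose mean OOB error is within
#' one SD of the global minimum, `"min"` the global minimum itself.
#'
#' @param features samples x features matrix (e.g. from [expand_ratios()]).
#' @param outcome numeric outcome, no missing values.
#' @param n_forests_per_step forests averaged per step (default 10).
#' @param drop_fraction fraction dropped per step (default 0.10).
#' @param floor stopping feature count (default 3).
#' @param ntree trees per selection forest (default 200).
#' @param mtry_factor multiplier for [rf_mtry()] (default 3).
#' @param cut_rule `"1se"` or `"min"`.
#' @param seed master seed for this selection run; forest seeds are derived
#'   from it with [derive_seed()].
#' @return list with `trace` (one row per step: `step`, `n_features`,
#'   `oob_mean`, `oob_sd`, `dropped` as a comma-joined string),
#'   `importances` (per-step named vectors over surviving features),
#'   `cut_step`, and `selected` (feature IDs surviving at the cut).
#' @export
iterative_selection <- function(features, outcome,
                                n_forests_per_step = 10,
                                drop_fraction = 0.10, floor = 3,
                                ntree = 200, mtry_factor = 3,
                                cut_rule = c("min", "1se"), seed = 1L) {
  cut_rule <- match.arg(cut_rule)
  stopifnot(nrow(features) == length(outcome), ncol(features) >= 4)
  if (anyNA(outcome)) stop("outcome contains missing values")
  if (stats::var(outcome) == 0) stop("outcome is constant")
  keep <- colnames(features)
  counter <- 0L
  steps <- list()
  importances <- list()
  survivors <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    p <- length(keep)
    imp <- numeric(p)
    oob <- numeric(n_forests_per_step)
    for (f in seq_len(n_forests_per_step)) {
      counter <- counter + 1L
      fit <- ranger::ranger(
        x = features[, keep, drop = FALSE], y = outcome,
        num.trees = ntree, mtry = rf_mtry(p, mtry_factor),
        importance = "impurity", num.threads = 1,
        seed = derive_seed(seed, counter))
      imp <- imp + fit$variable.importance
      oob[f] <- fit$prediction.error
    }
    imp <- imp / n_forests_per_step
    names(imp) <- keep
    importances[[step]] <- imp
    survivors[[step]] <- keep
    done <- p <= floor
    dropped <- character(0)
    if (!done) {
      n_drop <- max(1L, base::floor(drop_fraction * p))
      ord <- order(imp, keep)  # lowest importance first, ties by ID
      dropped <- keep[ord[seq_len(n_drop)]]
      keep <- keep[!keep %in% dropped]
    }
    steps[[step]] <- data.frame(
      step = step, n_features = p, oob_mean = mean(oob),
      oob_sd = stats::sd(oob), dropped = paste(dropped, collapse = ","),
      stringsAsFactors = FALSE)
    if (done) break
  }
  trace <- do.call(rbind, steps)
  i_min <- which.min(trace$oob_mean)
  cut_step <- if (cut_rule == "min") {
    i_min
  } else {
    thr <- trace$oob_mean[i_min] + trace$oob_sd[i_min]
    eligible <- which(trace$oob_mean <= thr)
    eligible[which.min(trace$n_features[eligible])]
  }
  list(trace = trace, importances = importances, cut_step = cut_step,
       selected = survivors[[cut_step]], cut_rule = cut_rule, seed = seed)
}

#' Fit the final severity random forest
#'
#' One regression forest on the selected features with the production tree
#' count and `mtry = 3 * sqrt(p)` (rounded half up, clipped to `[1, p]`).
#'
#' @param features samples x features matrix restricted or restrictable to
#'   the selected features.
#' @param outcome numeric outcome.
#' @param selected feature IDs to use (default: all columns).
#' @param ntree number of trees (default 40000).
#' @param mtry_factor multiplier for [rf_mtry()].
#' @param seed forest seed.
#' @param keep_inbag store per-tree inbag counts (needed to audit OOB
#'   predictions; off by default).
#' @param outcome_name label carried into reports.
#' @return Object of class `"severity_forest"`.
#' @export
fit_severity_forest <- function(features, outcome, selected = colnames(features),
                                ntree = 40000, mtry_factor = 3, seed = 1L,
                                keep_inbag = FALSE, outcome_name = "severity") {
  absent <- setdiff(selected, colnames(features))
  if (length(absent)) stop("features missing from matrix: ",
                           paste(absent, collapse = ", "))
  X <- features[, selected, drop = FALSE]
  fit <- ranger::ranger(x = X, y = outcome, num.trees = ntree,
                        mtry = rf_mtry(ncol(X), mtry_factor),
                        importance = "impurity", num.threads = 1,
                        seed = seed, keep.inbag = keep_inbag)
  structure(list(
    forest = fit, features = selected,
    analytes = feature_analytes(selected),
    outcome_name = outcome_name, ntree = ntree,
    mtry = rf_mtry(ncol(X), mtry_factor), seed = seed,
    oob_predictions = fit$predictions,
    observed = outcome,
    selection = NULL
  ), class = "severity_forest")
}

#' Train a CSF severity model (selection + final forest)
#'
#' The package's main fitting entry point: runs
#' [iterative_selection()] over the full ratio-expanded feature set, then
#' fits the final forest ([fit_severity_forest()]) on the features surviving
#' at the OOB cut.
#'
#' @inheritParams iterative_selection
#' @param ntree_selection trees per selection forest.
#' @param ntree_final trees in the final forest.
#' @param outcome_name label carried into reports.
#' @param keep_inbag see [fit_severity_forest()].
#' @return A `"severity_forest"` whose `selection` element holds the full
#'   elimination trace.
#' @export
train_severity_model <- function(features, outcome, outcome_name = "severity",
                                 n_forests_per_step = 10,
                                 drop_fraction = 0.10, floor = 3,
                                 ntree_selection = 200, ntree_final = 40000,
                                 mtry_factor = 3, cut_rule = c("min", "1se"),
                                 seed = 1L, keep_inbag = FALSE) {
  sel <- iterative_selection(features, outcome,
                             n_forests_per_step = n_forests_per_step,
                             drop_fraction = drop_fraction, floor = floor,
                             ntree = ntree_selection,
                             mtry_factor = mtry_factor,
                             cut_rule = cut_rule, seed = seed)
  model <- fit_severity_forest(features, outcome, selected = sel$selected,
                               ntree = ntree_final,
                               mtry_factor = mtry_factor,
                               seed = derive_seed(seed, 999983L),
                               keep_inbag = keep_inbag,
                               outcome_name = outcome_name)
  model$selection <- sel
  model
}

# Compute the values of given single/ratio features from an analyte panel.
compute_features <- function(panel, feature_ids) {
  need <- feature_analytes(feature_ids)
  absent <- setdiff(need, colnames(panel))
  if (length(absent)) stop("panel is missing analytes: ",
                           paste(absent, collapse = ", "))
  out <- matrix(0, nrow(panel), length(feature_ids),
                dimnames = list(rownames(panel), feature_ids))
  parts <- strsplit(feature_ids, "/", fixed = TRUE)
  for (i in seq_along(parts)) {
    pr <- parts[[i]]
    out[, i] <- if (length(pr) == 1) panel[, pr] else panel[, pr[1]] - panel[, pr[2]]
  }
  out
}

#' Predict severity from a fitted forest
#'
#' @param object a `"severity_forest"`.
#' @param newdata samples x features matrix containing the model features,
#'   or an analyte panel from which they can be computed. `NULL` returns the
#'   out-of-bag predictions for the training samples (each sample predicted
#'   only by trees whose bootstrap excluded it).
#' @param ... unused.
#' @return Numeric predictions, named by sample where available.
#' @export
predict.severity_forest <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$oob_predictions)
  if (!all(object$features %in% colnames(newdata))) {
    newdata <- compute_features(newdata, object$features)
  }
  pr <- stats::predict(object$forest,
                       data = newdata[, object$features, drop = FALSE],
                       num.threads = 1)
  stats::setNames(pr$predictions, rownames(newdata))
}

#' @export
print.severity_forest <- function(x, ...) {
  cat(sprintf("CSF severity random forest ('%s')\n", x$outcome_name))
  cat(sprintf("  %d selected features over %d unique analytes; ntree = %d, mtry = %d\n",
              length(x$features), length(x$analytes), x$ntree, x$mtry))
  if (!is.null(x$selection)) {
    tr <- x$selection$trace
    cat(sprintf("  elimination: %d steps from %d features; OOB cut ('%s' rule) at %d features (OOB MSE %.4g)\n",
                nrow(tr), tr$n_features[1], x$selection$cut_rule,
                tr$n_features[x$selection$cut_step],
                tr$oob_mean[x$selection$cut_step]))
  }
  invisible(x)
}

#' @export
summary.severity_forest <- function(object, ...) {
  rep <- evaluate_predictions(object$observed, object$oob_predictions)
  cat(sprintf("Training (OOB) performance for '%s':\n", object$outcome_name))
  cat(sprintf("  Spearman rho %.3f (p = %.3g), R^2 %.3f, CCC %.3f, n = %d\n",
              rep$spearman_rho, rep$spearman_p, rep$r_squared, rep$ccc, rep$n))
  invisible(rep)
}

#' Plot the out-of-bag error trace of the backward elimination
#'
#' @param x a `"severity_forest"` fitted by [train_severity_model()].
#' @param ... passed to [plot()].
#' @export
plot.severity_forest <- function(x, ...) {
  if (is.null(x$selection)) stop("model carries no selection trace")
  tr <- x$selection$trace
  plot(tr$n_features, tr$oob_mean, log = "x", type = "b", pch = 16,
       xlab = "number of features", ylab = "OOB mean squared error", ...)
  graphics::arrows(tr$n_features, tr$oob_mean - tr$oob_sd,
                   tr$n_features, tr$oob_mean + tr$oob_sd,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::abline(v = tr$n_features[x$selection$cut_step], lty = 2,
                   col = "red")
  invisible(x)
}
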