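#' Train a CSF proteomic aging clock
#'
#' Elastic-net regression of chronological age on standardized log-RFU
#' analyte values, trained on healthy volunteers only. Standardization
#' parameters and the penalty are derived from the training data alone
#' (leave-one-out cross-validation, suited to a small HV cohort), so
#' downstream predictions for MS samples are pure functions of the frozen
#' model.
#'
#' @param panel training samples x analytes log-RFU matrix (HV).
#' @param ages chronological ages of the training samples.
#' @param alpha elastic-net mixing parameter (0 = ridge, 1 = lasso);
#'   default 0.5.
#' @param lambda_rule `"1se"` (largest penalty within one SE of the CV
#'   minimum; guards overfit at small n) or `"min"`.
#' @param seed optional seed (leave-one-out CV itself is deterministic; the
#'   seed only fixes glmnet internals).
#' @param ... further arguments to [glmnet::cv.glmnet()] (e.g.
#'   `lambda.min.ratio` to extend the penalty path).
#' @return Object of class `"age_clock"` with standardized coefficients,
#'   intercept, chosen penalty, standardization means/SDs and training fit.
#' @export
train_age_clock <- function(panel, ages, alpha = 0.5,
                            lambda_rule = c("1se", "min"), seed = NULL, ...) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(nrow(panel) == length(ages))
  if (nrow(panel) < 10) stop("aging clock needs at least 10 training samples")
  if (stats::var(ages) == 0) stop("training ages are constant")
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(panel)
  sd <- apply(panel, 2, stats::sd)
  sd[sd == 0] <- 1
  X <- scale(panel, center = mu, scale = sd)
  n <- nrow(X)
  cv <- glmnet::cv.glmnet(X, ages, alpha = alpha, nfolds = n,
                          foldid = seq_len(n), grouped = FALSE,
                          standardize = FALSE, ...)
  lambda <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  co <- as.matrix(stats::coef(cv, s = lambda))
  fitted <- as.vector(co[1] + X %*% co[-1, , drop = FALSE])
  r2 <- if (stats::var(fitted) > 0) stats::cor(fitted, ages)^2 else 0
  structure(list(
    coefficients = stats::setNames(co[-1, 1], colnames(panel)),
    intercept = co[1, 1], alpha = alpha, lambda = lambda,
    lambda_rule = lambda_rule, center = mu, scale = sd,
    train_r2 = r2, train_fitted = fitted, n_train = n
  ), class = "age_clock")
}

#' @export
print.age_clock <- function(x, ...) {
  cat("CSF proteomic aging clock (elastic net)\n")
  cat(sprintf("  %d training samples, %d analytes, %d nonzero coefficients\n",
              x$n_train, length(x$coefficients), sum(x$coefficients != 0)))
  cat(sprintf("  alpha = %.2f, lambda = %.4g (%s rule), in-sample R^2 = %.3f\n",
              x$alpha, x$lambda, x$lambda_rule, x$train_r2))
  invisible(x)
}

#' @export
coef.age_clock <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict age from a proteomic panel
#'
#' @param object an `"age_clock"` model.
#' @param panel samples x analytes log-RFU matrix containing every model
#'   analyte.
#' @param ... unused.
#' @return Numeric vector of predicted ages (years), named by sample.
#' @export
predict.age_clock <- function(object, panel, ...) {
  absent <- setdiff(names(object$coefficients), colnames(panel))
  if (length(absent)) stop("panel is missing model analytes: ",
                           paste(absent, collapse = ", "))
  X <- scale(panel[, names(object$coefficients), drop = FALSE],
             center = object$center, scale = object$scale)
  stats::setNames(as.vector(object$intercept + X %*% object$coefficients),
                  rownames(panel))
}

#' Pairwise delta-age contrasts between diagnostic groups
#'
#' Delta age = predicted - observed. All group pairs are compared with
#' two-sided Wilcoxon rank-sum tests, Benjamini-Hochberg adjusted across the
#' pairwise family; group medians are reported. Groups with fewer than 2
#' members are excluded with a warning.
#'
#' @param predicted,observed ages, same length.
#' @param groups group labels (factor or character).
#' @return data.frame with one row per group pair.
#' @export
compare_delta_age <- function(predicted, observed, groups) {
  stopifnot(length(predicted) == length(observed),
            length(groups) == length(predicted))
  delta <- predicted - observed
  groups <- factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("groups excluded (n < 2): ", paste(small, collapse = ", "))
    keep <- !groups %in% small
    delta <- delta[keep]
    groups <- droplevels(groups[keep])
  }
  lv <- levels(groups)
  if (length(lv) < 2) stop("need at least 2 groups of size >= 2")
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    w <- suppressWarnings(stats::wilcox.test(delta[groups == g1],
                                             delta[groups == g2],
                                             alternative = "two.sided"))
    data.frame(group1 = g1, group2 = g2,
               median_delta1 = stats::median(delta[groups == g1]),
               median_delta2 = stats::median(delta[groups == g2]),
               p_value = w$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out
}
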