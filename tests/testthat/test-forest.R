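test_that("ratio expansion emits one orientation per unordered pair", {
  panel <- matrix(1:6 + 0.0, 2, 3, dimnames = list(c("s1", "s2"),
                                                   c("B", "A", "C")))
  f <- expand_ratios(panel)
  expect_setequal(colnames(f), c("B", "A", "C", "A/B", "A/C", "B/C"))
  expect_equal(f[, "A/B"], panel[, "A"] - panel[, "B"])
  expect_equal(f[, "A/B"], -(panel[, "B"] - panel[, "A"]))
  expect_equal(ncol(f), n_ratio_features(3))
  expect_equal(n_ratio_features(1305), 852165)
  expect_error(expand_ratios(panel[, c(1, 1)]), "duplicate")
  expect_setequal(feature_analytes(c("A/B", "C")), c("A", "B", "C"))
})

test_that("the elimination schedule is the deterministic 10% iteration", {
  expect_equal(elimination_schedule(10), c(10, 9, 8, 7, 6, 5, 4, 3))
  # independent oracle: iterate p <- p - max(1, floor(0.1 p))
  oracle <- function(p) {
    out <- p
    while (p > 3) { p <- p - max(1, floor(0.1 * p)); out <- c(out, p) }
    out
  }
  expect_equal(elimination_schedule(100), oracle(100))
  expect_equal(length(elimination_schedule(100)), 34)
  expect_equal(tail(elimination_schedule(100), 2), c(4, 3))
  expect_equal(elimination_schedule(1890)[2], 1701)
  expect_equal(elimination_schedule(3), 3)
})

test_that("mtry follows 3*sqrt(p) rounded half up and clipped", {
  expect_equal(rf_mtry(57), 23L)
  expect_equal(rf_mtry(1), 1L)
  expect_equal(rf_mtry(4), 4L)         # 3*2 = 6 clipped to p = 4
  expect_equal(rf_mtry(1890), 130L)
})

test_that("iterative selection traces the schedule and is seed-reproducible", {
  set.seed(1)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("F%d", 1:6)))
  y <- X[, 1] + rnorm(n, 0, 0.1)
  feats <- expand_ratios(X)                       # 21 features
  sel <- iterative_selection(feats, y, ntree = 50, seed = 5)
  expect_equal(sel$trace$n_features, elimination_schedule(21))
  expect_false(any(is.na(sel$trace$oob_sd)))
  expect_true(all(diff(sel$trace$n_features) < 0))
  sel2 <- iterative_selection(feats, y, ntree = 50, seed = 5)
  expect_identical(sel$trace, sel2$trace)
  expect_identical(sel$selected, sel2$selected)
  # the informative single feature survives to the cut
  expect_true("F1" %in% feature_analytes(sel$selected))
  expect_error(iterative_selection(feats, rep(1, n), ntree = 50), "constant")
})

test_that("selection on a pure-noise outcome cannot beat the outcome variance", {
  n <- 50
  mins <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, sprintf("F%d", 1:8)))
    y <- rnorm(n)
    sel <- iterative_selection(expand_ratios(X), y, ntree = 60, seed = s)
    min(sel$trace$oob_mean) / var(y)
  }, 0)
  expect_gt(mean(mins), 0.9)
})

test_that("deep forests near-interpolate a noiseless training signal", {
  set.seed(2)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, sprintf("F%d", 1:4)))
  y <- X[, 1] + 0.5 * X[, 2]
  fit <- fit_severity_forest(X, y, ntree = 500, seed = 3)
  pred <- predict(fit, X)
  expect_gt(cor(pred, y)^2, 0.95)
  # same seed, bit-identical predictions
  fit2 <- fit_severity_forest(X, y, ntree = 500, seed = 3)
  expect_identical(predict(fit2, X), pred)
  # constant outcome: every prediction equals it
  fitc <- fit_severity_forest(X, rep(2.5, n), ntree = 50, seed = 1)
  expect_equal(unname(predict(fitc, X)), rep(2.5, n))
})

test_that("OOB predictions use only trees whose bootstrap excluded the sample", {
  set.seed(4)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, sprintf("F%d", 1:3)))
  y <- X[, 1] + rnorm(n, 0, 0.2)
  fit <- fit_severity_forest(X, y, ntree = 100, seed = 7, keep_inbag = TRUE)
  per_tree <- predict(fit$forest, data = as.data.frame(X), predict.all = TRUE,
                      num.threads = 1)$predictions
  inbag <- simplify2array(fit$forest$inbag.counts)  # n x ntree
  manual <- vapply(seq_len(n), function(i) {
    oob_trees <- inbag[i, ] == 0
    mean(per_tree[i, oob_trees])
  }, 0)
  expect_equal(unname(predict(fit)), manual, tolerance = 1e-12)
})

test_that("tree splits are invariant to the monotone log <-> ratio transform", {
  set.seed(5)
  n <- 50
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, sprintf("F%d", 1:5)))
  y <- X[, 1] - X[, 2] + rnorm(n, 0, 0.1)
  feats <- expand_ratios(X)
  f1 <- fit_severity_forest(feats, y, ntree = 100, seed = 11)
  f2 <- fit_severity_forest(exp(feats), y, ntree = 100, seed = 11)
  # split search depends only on the value ordering; agreement is exact up
  # to floating-point ties between near-equal candidate splits
  p1 <- unname(predict(f1)); p2 <- unname(predict(f2))
  expect_gt(cor(p1, p2), 0.99)
  expect_lt(mean(abs(p1 - p2)) / sd(p1), 0.05)
})

test_that("the fitted bundle records its unique-analyte decomposition", {
  set.seed(6)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, sprintf("F%d", 1:5)))
  y <- X[, 1] - X[, 3] + rnorm(n, 0, 0.2)
  mod <- train_severity_model(expand_ratios(X), y, ntree_selection = 60,
                              ntree_final = 300, seed = 9)
  expect_s3_class(mod, "severity_forest")
  expect_identical(mod$analytes, feature_analytes(mod$features))
  expect_identical(mod$selection$trace$n_features[mod$selection$cut_step],
                   length(mod$features))
  # predictions computable straight from an analyte panel
  expect_equal(predict(mod, expand_ratios(X)), predict(mod, X))
})
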