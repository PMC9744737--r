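test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Spearman screen is exact on monotone relationships and
           invariant to monotone transforms", {
  set.seed(2)
  panel <- matrix(rnorm(200), 50, 4,
                  dimnames = list(NULL, sprintf("APT%04d", 1:4)))
  y <- exp(panel[, 1])          # strictly increasing transform of analyte 1
  res <- correlate_outcomes(panel, data.frame(sev = y))
  expect_equal(res$spearman_rho[res$analyte_id == "APT0001"], 1)

  res2 <- correlate_outcomes(cbind(panel, APTMONO = panel[, 2]^3),
                             data.frame(sev = y))
  expect_equal(res2$spearman_rho[res2$analyte_id == "APTMONO"],
               res2$spearman_rho[res2$analyte_id == "APT0002"])

  # Spearman equals Pearson on ranks
  expect_equal(res$spearman_rho[2],
               cor(rank(panel[, 2]), rank(y)), tolerance = 1e-12)
})

test_that("screen handles degenerate inputs per contract", {
  panel <- matrix(c(rnorm(20), rep(1, 20)), 20, 2,
                  dimnames = list(NULL, c("APTOK", "APTFLAT")))
  y <- rnorm(20)
  expect_warning(res <- correlate_outcomes(panel, data.frame(sev = y)),
                 "APTFLAT")
  expect_true(is.nan(res$spearman_rho[res$analyte_id == "APTFLAT"]))
  expect_error(correlate_outcomes(panel, data.frame(sev = rep(1, 20))),
               "constant")
  expect_error(correlate_outcomes(panel[1:3, ], data.frame(sev = y[1:3])),
               "fewer than 4")
})

test_that("enrichment exports are ordered and split by sign", {
  set.seed(3)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1 - x2 + rnorm(n, 0, 0.4)
  panel <- cbind(APTPOS = x1, APTNEG = x2,
                 matrix(rnorm(3 * n), n, 3,
                        dimnames = list(NULL, sprintf("APTN%02d", 1:3))))
  res <- correlate_outcomes(panel, data.frame(sev = y))
  d <- tempfile()
  files <- rank_for_enrichment(res, d)
  by_p <- readLines(file.path(d, "ranked_sev_by_p.txt"))
  p_of <- res$p_value[match(by_p, res$analyte_id)]
  expect_false(is.unsorted(p_of))
  expect_true("APTPOS" %in% readLines(file.path(d, "ranked_sev_pos.txt")))
  expect_true("APTNEG" %in% readLines(file.path(d, "ranked_sev_neg.txt")))

  # no significant analytes: empty sublists, full ordered lists
  null_res <- res
  null_res$fdr_q <- 1
  d2 <- tempfile()
  rank_for_enrichment(null_res, d2)
  expect_length(readLines(file.path(d2, "ranked_sev_pos.txt")), 0)
  expect_length(readLines(file.path(d2, "ranked_sev_by_rho.txt")), 5)

  # unmapped analytes fall back to their aptamer IDs with a warning
  d3 <- tempfile()
  expect_warning(rank_for_enrichment(res, d3, mapping = c(APTPOS = "GENE1")),
                 "unmapped")
  expect_true(all(c("GENE1", "APTNEG") %in%
                    readLines(file.path(d3, "ranked_sev_by_p.txt"))))
})

test_that("planted severity-module analytes are detected by the screen", {
  cfg <- simulation_config(seed = 13)
  sim <- simulate_cohort(cfg)
  ms <- sim$metadata$cohort == "MS"
  res <- correlate_outcomes(sim$panel[ms, ],
                            sim$metadata[ms, "msdss_baseline", drop = FALSE])
  drivers <- sim$truth$analytes$analyte_id[
    sim$truth$analytes$severity_weight != 0]
  hits <- res$analyte_id[res$fdr_q < 0.05]
  expect_gte(length(intersect(hits, drivers)), 0.6 * length(drivers))
  pos <- res$spearman_rho[match(drivers, res$analyte_id)]
  expect_true(all(pos > 0))
})
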