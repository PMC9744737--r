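test_that("Lin's CCC matches closed forms and the brute-force oracle", {
  x <- c(1, 2, 3)
  expect_equal(concordance_ccc(x, x), 1)
  expect_equal(concordance_ccc(x, c(2, 3, 4)), 4 / 7)
  expect_equal(concordance_ccc(x, -x + 2 * mean(x)), -1)
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(concordance_ccc(a, b), ccc_oracle(a, b), tolerance = 1e-12)
    expect_lte(abs(concordance_ccc(a, b)), abs(cor(a, b)) + 1e-12)
    expect_equal(concordance_ccc(a, b), concordance_ccc(b, a),
                 tolerance = 1e-12)
  }
  expect_warning(res <- concordance_ccc(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.nan(res))
})

test_that("prediction evaluation reports rho, R^2 and CCC coherently", {
  set.seed(2)
  obs <- rnorm(40, 0, 2)
  ev <- evaluate_predictions(obs, obs)
  expect_equal(ev$spearman_rho, 1)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$ccc, 1)

  shifted <- evaluate_predictions(obs, obs + 1)
  s2 <- var(obs) * (length(obs) - 1) / length(obs)
  expect_equal(shifted$ccc, 2 * s2 / (2 * s2 + 1), tolerance = 1e-12)
  expect_equal(shifted$r_squared, 1)

  rev_ranks <- sort(obs, decreasing = TRUE)[rank(obs)]
  expect_equal(evaluate_predictions(obs, rev_ranks)$spearman_rho, -1)

  sym <- evaluate_predictions(obs + rnorm(40), obs)
  sym2 <- evaluate_predictions(obs, obs + rnorm(40))
  ev_a <- evaluate_predictions(obs, exp(obs / 2))
  ev_b <- evaluate_predictions(exp(obs / 2), obs)
  expect_equal(ev_a$spearman_rho, ev_b$spearman_rho)
  expect_equal(ev_a$r_squared, ev_b$r_squared)
  expect_equal(ev_a$ccc, ev_b$ccc)

  expect_error(evaluate_predictions(c(1, NA, 3, 4), 1:4), "missing")
})

test_that("progression validation ranks an informative predictor above noise", {
  set.seed(3)
  wins <- 0
  for (s in 1:20) {
    latent <- rnorm(100)
    slope <- latent + rnorm(100)
    preds <- data.frame(model = latent + rnorm(100, 0, 0.5),
                        noise = rnorm(100))
    out <- validate_progression(preds, slope)
    wins <- wins + (out$spearman_rho[out$predictor == "model"] >
                      out$spearman_rho[out$predictor == "noise"])
  }
  expect_gte(wins, 18)
})

test_that("progression validation adjusts across the family and skips
           short predictors", {
  set.seed(4)
  slope <- rnorm(30)
  preds <- data.frame(a = rnorm(30), b = rnorm(30))
  preds$dup <- preds$a
  out <- validate_progression(preds, slope)
  expect_equal(out$fdr_q, bh_oracle(out$p_value), tolerance = 1e-12)
  expect_equal(out$spearman_rho[out$predictor == "a"],
               out$spearman_rho[out$predictor == "dup"])
  preds$short <- c(rnorm(3), rep(NA, 27))
  expect_warning(out2 <- validate_progression(preds, slope), "short")
  expect_false("short" %in% out2$predictor)
})

test_that("cohort balance reproduces the published sex-balance example", {
  md_tr <- data.frame(sex = rep(c("F", "M"), c(69, 60)),
                      age = rnorm(129, 48, 10))
  md_va <- data.frame(sex = rep(c("F", "M"), c(54, 44)),
                      age = rnorm(98, 48, 10))
  out <- compare_cohorts(md_tr, md_va, vars = "age")
  sex_p <- out$p_value[out$variable == "sex"]
  # frozen value for a 69F/60M vs 54F/44M split under Yates correction
  expect_lt(abs(sex_p - 0.9146), 0.001)
  chi_oracle <- chisq.test(rbind(c(69, 60), c(54, 44)), correct = TRUE)
  expect_equal(sex_p, chi_oracle$p.value, tolerance = 1e-12)

  same <- compare_cohorts(md_tr, md_tr, vars = "age")
  expect_equal(same$p_value[same$variable == "sex"], 1)

  big_tr <- data.frame(sex = rep(c("F", "M"), c(90, 10)))
  big_va <- data.frame(sex = rep(c("F", "M"), c(10, 90)))
  expect_lt(compare_cohorts(big_tr, big_va, vars = character(0))$p_value[1],
            1e-10)
})
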