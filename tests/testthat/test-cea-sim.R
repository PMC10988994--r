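prostate_counts <- stratum_counts(6155, 144032, label = "all")
prostate_effects <- effect_input(134, c(-217, 485), -2.68, c(-7.48, 2.12),
                                 source = "mendelian_randomization")

test_that("case proportions carry the binomial standard error", {
  ps <- proportion_se(prostate_counts)
  expect_equal(round(100 * ps$proportion, 1), 4.3)
  expect_equal(ps$se, sqrt(ps$proportion * (1 - ps$proportion) / 144032))

  half <- proportion_se(stratum_counts(100, 200))
  expect_equal(half$proportion, 0.5)
  expect_equal(half$se, 0.5 / sqrt(200))

  # Monte-Carlo oracle: the SE matches the sampling SD of binomial proportions
  set.seed(60)
  emp <- sd(rbinom(1e6, 200, 0.25) / 200)
  expect_equal(proportion_se(stratum_counts(50, 200))$se, emp,
               tolerance = 0.01)

  expect_error(stratum_counts(0, 10), "n_cases")
  expect_error(stratum_counts(10, 10), "n_cases")
})

test_that("the odds-ratio to risk-difference conversion is exact", {
  expect_equal(round(100 * or_to_risk_difference(prostate_counts, 0.29), 1),
               -3.0)
  expect_equal(or_to_risk_difference(prostate_counts, 1), 0)
  expect_lt(or_to_risk_difference(prostate_counts, 0.5), 0)
  expect_gt(or_to_risk_difference(prostate_counts, 2), 0)

  # algebraic oracle: odds transform, scale, back-transform
  set.seed(61)
  for (i in 1:20) {
    N <- sample(1000:100000, 1)
    n <- sample(seq_len(N - 1), 1)
    or <- exp(rnorm(1, 0, 0.7))
    p <- n / N
    odds <- p / (1 - p)
    p_new <- (odds * or) / (1 + odds * or)
    expect_equal(or_to_risk_difference(stratum_counts(n, N), or),
                 p_new - p, tolerance = 1e-12)
  }
  expect_error(or_to_risk_difference(prostate_counts, -1), "positive")
})

test_that("drug costs annualise by simple multiplication", {
  expect_equal(annualise_drug_cost(39.20), 470.40)
  expect_equal(round(annualise_drug_cost(39.20)), 470)
  expect_equal(annualise_drug_cost(0), 0)
  expect_equal(annualise_drug_cost(10), 120)
  expect_error(annualise_drug_cost(-1), "non-negative")
})

test_that("net monetary benefit follows its definition", {
  expect_equal(nmb(0, 0, 20000), 0)
  expect_equal(nmb(100, 0.01, 20000), 100)
  set.seed(62)
  for (i in 1:20) {
    dc <- rnorm(1, 0, 500)
    dq <- rnorm(1, 0, 0.05)
    th <- runif(1, 1000, 50000)
    expect_equal(nmb(dc, dq, th), th * dq - dc)
  }
})

test_that("degenerate draws collapse to the point calculation", {
  null_eff <- effect_input(0, c(0, 0), 0, c(0, 0))
  for (seed in c(1, 999)) {
    spec <- intervention_spec(0.29, c(0.13, 0.65), 470, n_draws = 500,
                              seed = seed)
    res <- run_intervention_sim(spec, null_eff, prostate_counts)
    s <- res$summary
    expect_equal(s$median[s$quantity == "delta_cost"], 470)
    expect_equal(s$median[s$quantity == "nmb"], -470)
  }

  # OR = 1 with a zero-width CI: no risk change, NMB = -drug cost
  spec1 <- intervention_spec(1, c(1, 1), 470, n_draws = 500, seed = 3)
  res1 <- run_intervention_sim(spec1, prostate_effects, prostate_counts,
                               keep_draws = TRUE)
  expect_true(all(abs(res1$draws[, "risk_difference"]) < 1e-6))
  expect_equal(res1$summary$median[res1$summary$quantity == "nmb"], -470,
               tolerance = 1e-3)
})

test_that("point-estimate mode reproduces the hand-arithmetic oracle", {
  # all uncertainty off: one draw at the point estimates
  spec <- intervention_spec(0.29, c(0.29, 0.29), 470.40, 20000, n_draws = 1,
                            seed = 1)
  eff <- effect_input(134, c(134, 134), -2.68, c(-2.68, -2.68))
  res <- run_intervention_sim(spec, eff, prostate_counts)

  rd <- or_to_risk_difference(prostate_counts, 0.29)
  oracle_cost <- 470.40 + rd * 134
  oracle_qaly <- rd * (-2.68)
  oracle_nmb <- oracle_qaly / 100 * 20000 - oracle_cost
  s <- res$summary
  # the medians are the single draw; the only residual randomness is the
  # intrinsic binomial SE of the case proportion, worth well under GBP 1
  expect_lt(abs(s$median[s$quantity == "delta_cost"] - oracle_cost), 1)
  expect_lt(abs(s$median[s$quantity == "delta_qaly"] - oracle_qaly), 0.01)
  expect_lt(abs(s$median[s$quantity == "nmb"] - oracle_nmb), 1)
  expect_true(all(s$ci_lower <= s$median & s$median <= s$ci_upper))
})

test_that("median NMB decreases one-for-one with the drug price", {
  eff <- prostate_effects
  s1 <- intervention_spec(0.29, c(0.13, 0.65), 470.40, n_draws = 2000,
                          seed = 7)
  s2 <- intervention_spec(0.29, c(0.13, 0.65), 570.40, n_draws = 2000,
                          seed = 7)
  r1 <- run_intervention_sim(s1, eff, prostate_counts)
  r2 <- run_intervention_sim(s2, eff, prostate_counts)
  n1 <- r1$summary$median[r1$summary$quantity == "nmb"]
  n2 <- r2$summary$median[r2$summary$quantity == "nmb"]
  expect_equal(n1 - n2, 100, tolerance = 1e-9)
})

test_that("the break-even price zeroes the median NMB when re-run", {
  spec <- intervention_spec(0.29, c(0.13, 0.65), 470.40, n_draws = 5000,
                            seed = 11)
  res <- run_intervention_sim(spec, prostate_effects, prostate_counts)
  expect_lt(abs(res$breakeven_verified_nmb), 1)
})

test_that("risk-difference draws respect their lower bound", {
  spec <- intervention_spec(1e-6, c(1e-6, 1e-6), 470, n_draws = 2000,
                            seed = 13)
  res <- run_intervention_sim(spec, prostate_effects, prostate_counts,
                              keep_draws = TRUE)
  ps <- proportion_se(prostate_counts)
  rd <- res$draws[, "risk_difference"]
  expect_true(all(rd > -1))
  expect_true(all(rd >= -(ps$proportion + 6 * ps$se)))
})

test_that("medians are stable across independent simulation runs", {
  eff <- prostate_effects
  r1 <- run_intervention_sim(
    intervention_spec(0.29, c(0.13, 0.65), 470.40, n_draws = 10000, seed = 21),
    eff, prostate_counts)
  r2 <- run_intervention_sim(
    intervention_spec(0.29, c(0.13, 0.65), 470.40, n_draws = 10000, seed = 22),
    eff, prostate_counts)
  n1 <- r1$summary$median[r1$summary$quantity == "nmb"]
  n2 <- r2$summary$median[r2$summary$quantity == "nmb"]
  expect_lt(abs(n1 - n2) / abs(n1), 0.01)
})

test_that("natural-scale odds-ratio drawing is available and positive", {
  spec <- intervention_spec(0.29, c(0.13, 0.65), 470.40, n_draws = 2000,
                            seed = 15, or_scale = "natural")
  res <- run_intervention_sim(spec, prostate_effects, prostate_counts,
                              keep_draws = TRUE)
  expect_true(all(is.finite(res$draws)))
  expect_true(all(res$draws[, "risk_difference"] > -1))
})

test_that("intervention and effect inputs validate their invariants", {
  expect_error(intervention_spec(-0.3, c(0.1, 0.5), 470), "positive")
  expect_error(intervention_spec(0.3, c(0.5, 0.1), 470), "ordered")
  expect_error(intervention_spec(0.3, c(0.1, 0.5), 470, n_draws = 0),
               "n_draws")
  expect_error(effect_input(100, c(200, 50), -1, c(-2, 0)), "cost_ci95")
  expect_error(effect_input(100, c(50, 200), -1, c(0, -2)), "qaly_ci95")
})
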