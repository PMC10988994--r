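test_that("just-identified 2SLS equals the Wald ratio without covariates", {
  sim <- quick_sim(3000, seed = 40, missing_rate = 0)
  z <- prs_of(sim)
  iv <- fit_2sls(sim$cohort$annual_cost, sim$cohort$cancer, z)
  wald <- stats::cov(sim$cohort$annual_cost, z) /
    stats::cov(sim$cohort$cancer, z)
  expect_equal(iv$beta, wald, tolerance = 1e-10)
})

test_that("regressing the exposure on itself is the identity", {
  sim <- quick_sim(500, seed = 41)
  z <- prs_of(sim)
  iv <- fit_2sls(sim$cohort$cancer, sim$cohort$cancer, z,
                 mr_covariates(sim$cohort))
  expect_equal(iv$beta, 1, tolerance = 1e-10)
  expect_equal(iv$se, 0, tolerance = 1e-8)
})

test_that("2SLS point estimates are invariant to instrument scale", {
  sim <- quick_sim(2000, seed = 42, missing_rate = 0)
  z <- prs_of(sim)
  C <- mr_covariates(sim$cohort)
  b1 <- fit_2sls(sim$cohort$annual_cost, sim$cohort$cancer, z, C)$beta
  b2 <- fit_2sls(sim$cohort$annual_cost, sim$cohort$cancer, z * 1000, C)$beta
  expect_lt(abs(b1 - b2) / abs(b1), 1e-9)
})

test_that("degenerate designs raise instead of returning NaN", {
  sim <- quick_sim(500, seed = 43)
  ch <- sim$cohort
  expect_error(fit_2sls(ch$annual_cost, ch$cancer, rep(1, 500)),
               "zero variance")
  C_bad <- cbind(mr_covariates(ch), dup = mr_covariates(ch)[, "age"])
  expect_error(fit_2sls(ch$annual_cost, ch$cancer, prs_of(sim), C_bad),
               "rank deficient")
  expect_error(fit_ols(ch$annual_cost, ch$cancer, C_bad), "rank deficient")
})

test_that("OLS under a null exposure is null; duplication halves robust SEs", {
  set.seed(44)
  y <- rnorm(1000)
  x <- rbinom(1000, 1, 0.3)  # independent of y by construction
  est <- fit_ols(y, x)
  expect_lt(abs(est$beta), 2 * est$se)

  sim <- quick_sim(400, seed = 45, missing_rate = 0)
  ch <- sim$cohort
  ch2 <- rbind(ch, ch)
  e1 <- fit_ols(ch$annual_cost, ch$cancer, mr_covariates(ch))
  e2 <- fit_ols(ch2$annual_cost, ch2$cancer, mr_covariates(ch2))
  expect_equal(e2$beta, e1$beta, tolerance = 1e-10)
  expect_equal(e2$se / e1$se, 1 / sqrt(2), tolerance = 0.05)
})

test_that("confounding biases OLS away from truth but not 2SLS", {
  reps <- 30
  ols_high <- 0L
  iv_err <- ols_err <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- quick_sim(4000, seed = 300 + r, beta_cost = 800,
                     cost_baseline = 3000,
                     confounder_effects = c(1.5, 1200, -0.1),
                     missing_rate = 0)
    iv <- fit_iv_cost(sim)
    ols <- fit_ols_cost(sim)
    if (ols$beta > 800) ols_high <- ols_high + 1L  # positive confounding
    iv_err[r] <- iv$beta - 800
    ols_err[r] <- ols$beta - 800
  }
  expect_gte(ols_high / reps, 0.9)
  expect_lt(abs(median(iv_err)), abs(median(ols_err)))
})

test_that("the Hausman test behaves at its boundaries", {
  iv <- mr_estimate(100, 50, n = 1000, first_stage_f = 200,
                    outcome_label = "annual_cost", exposure_label = "cancer",
                    method = "2sls")
  ols <- mr_estimate(100, 10, n = 1000, outcome_label = "annual_cost",
                     exposure_label = "cancer", method = "ols")
  h <- hausman_test(iv, ols)
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)

  # non-positive variance difference clamps with a warning
  iv_small <- mr_estimate(120, 5, n = 1000, first_stage_f = 200,
                          outcome_label = "annual_cost",
                          exposure_label = "cancer", method = "2sls")
  expect_warning(h2 <- hausman_test(iv_small, ols), "clamped")
  expect_equal(h2$statistic, 0)
  expect_equal(h2$p_value, 1)

  ols_other <- mr_estimate(100, 10, n = 1000, outcome_label = "annual_qaly",
                           exposure_label = "cancer", method = "ols")
  expect_error(hausman_test(iv, ols_other), "mismatched")
  expect_error(hausman_test(ols, ols), "2SLS")
})

test_that("Hausman rejects under strong confounding", {
  rej <- 0L
  reps <- 25
  for (r in seq_len(reps)) {
    sim <- quick_sim(20000, seed = 500 + r, beta_cost = 800,
                     cost_baseline = 3000,
                     confounder_effects = c(1.5, 1200, -0.1),
                     missing_rate = 0, n_pcs = 2)
    h <- hausman_test(fit_iv_cost(sim), fit_ols_cost(sim))
    if (h$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.5)
})

test_that("first-stage F grows roughly linearly with n", {
  fs <- sapply(1:16, function(r) {
    s1 <- quick_sim(2500, seed = 600 + r, missing_rate = 0, n_pcs = 2)
    s2 <- quick_sim(5000, seed = 700 + r, missing_rate = 0, n_pcs = 2)
    c(fit_iv_cost(s1)$first_stage_f, fit_iv_cost(s2)$first_stage_f)
  })
  ratio <- mean(fs[2, ]) / mean(fs[1, ])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("QALY scaling to percentage points is elementwise", {
  expect_equal(as.numeric(scale_qaly(0.78)), 78)
  expect_equal(as.numeric(scale_qaly(0)), 0)
  x <- runif(20)
  expect_equal(as.numeric(scale_qaly(x)), sapply(x, function(v) v * 100))
  expect_identical(attr(scale_qaly(0.5), "units"), "% of a QALY per year")
})

test_that("stratified fits partition correctly and report skips", {
  sim <- quick_sim(4000, seed = 46, missing_rate = 0)

  # a single all-encompassing stratum reproduces the unstratified fit
  one <- stratified_mr(sim$cohort, sim$dosages, sim$weights,
                       variable = "custom",
                       custom = rep("all", nrow(sim$cohort)))
  expect_length(one$skipped, 0)
  expect_equal(one$estimates$all$beta, fit_iv_cost(sim)$beta,
               tolerance = 1e-10)

  # a stratum without both exposure classes is skipped, not dropped silently
  controls_only <- seq_len(nrow(sim$cohort)) <= 500 & sim$cohort$cancer == 0
  labels <- ifelse(controls_only, "pure_controls", "mixed")
  sk <- stratified_mr(sim$cohort, sim$dosages, sim$weights,
                      variable = "custom", custom = labels)
  expect_match(sk$skipped[["pure_controls"]], "one exposure class")
  expect_named(sk$estimates, "mixed")

  # sex strata drop the sex covariate and both fit
  by_sex <- stratified_mr(sim$cohort, sim$dosages, sim$weights,
                          variable = "sex")
  expect_setequal(names(by_sex$estimates), c("female", "male"))

  # age bands cover everyone
  by_age <- stratified_mr(sim$cohort, sim$dosages, sim$weights,
                          variable = "age_band", breaks = c(50, 60))
  ns <- vapply(by_age$estimates, `[[`, integer(1), "n")
  expect_equal(sum(ns), sum(!is.na(sim$cohort$annual_cost)))
})

test_that("stratum heterogeneity is null when effects are homogeneous", {
  qp <- numeric(12)
  for (r in seq_len(12)) {
    sim <- quick_sim(6000, seed = 800 + r, missing_rate = 0, n_pcs = 2)
    by_age <- stratified_mr(sim$cohort, sim$dosages, sim$weights,
                            variable = "age_band", breaks = c(50, 60))
    betas <- vapply(by_age$estimates, `[[`, numeric(1), "beta")
    ses <- vapply(by_age$estimates, `[[`, numeric(1), "se")
    qp[r] <- ivw_pool(betas, ses)$q_pvalue
  }
  # under homogeneity, between-stratum Q should rarely reject
  expect_lte(sum(qp < 0.05), 3)
})

test_that("negative controls enforce their preconditions", {
  sim <- quick_sim(2000, seed = 47, sex_specific = "male")
  z <- prs_of(sim)
  males_only <- sim$cohort[sim$cohort$sex == "male", ]
  expect_error(negative_control(males_only, z[sim$cohort$sex == "male"],
                                control_sex = "female"),
               "no individuals")
  expect_error(negative_control(sim$cohort, z, control_sex = "male"),
               "not a negative control")
  nc <- negative_control(sim$cohort, z, control_sex = "female")
  expect_named(nc, c("annual_cost", "annual_qaly"))
  expect_s3_class(nc$annual_cost, "mr_estimate")
})

test_that("substituting the cohort's own cancer score breaks the null", {
  # sanity inversion: among the sex that *can* express the cancer, the same
  # score is strongly associated with the cost outcome (cost noise kept low
  # so the per-score signal is detectable at this n)
  sim <- quick_sim(12000, seed = 48, sex_specific = "male",
                   missing_rate = 0, cost_noise_sd = 300, beta_cost = 1500,
                   true_log_or = rep(0.4, 10))
  z <- prs_of(sim)
  keep <- sim$cohort$sex == "male"
  own <- fit_ols(sim$cohort$annual_cost[keep], z[keep],
                 mr_covariates(sim$cohort[keep, ], drop_sex = TRUE))
  nc <- negative_control(sim$cohort, z, control_sex = "female")
  expect_gt(abs(own$beta / own$se), abs(nc$annual_cost$beta / nc$annual_cost$se))
  expect_gt(abs(own$beta / own$se), 2)
})

test_that("Rubin's-rules pooling is exact without missingness and inflates W", {
  sim0 <- quick_sim(1500, seed = 49, missing_rate = 0)
  single <- fit_iv_cost(sim0)
  pooled0 <- impute_and_pool(sim0$cohort, m = 5,
                             function(ch) fit_iv_cost(sim0))
  expect_identical(pooled0$beta, single$beta)
  expect_identical(pooled0$se, single$se)

  sim <- quick_sim(1500, seed = 49, missing_rate = 0.3)
  fit_fun <- function(ch) {
    fit_2sls(ch$annual_cost, ch$cancer, prs_of(sim), mr_covariates(ch),
             outcome_label = "annual_cost", exposure_label = "cancer")
  }
  pooled <- impute_and_pool(sim$cohort, m = 5, fit_fun, seed = 1)
  expect_gte(pooled$se^2, attr(pooled, "within_variance"))
  expect_equal(pooled$se^2,
               attr(pooled, "within_variance") +
                 (1 + 1 / 5) * attr(pooled, "between_variance"))
  expect_error(impute_and_pool(sim$cohort, m = 1, fit_fun), "at least 2")
  all_na <- sim$cohort
  all_na$annual_cost <- NA_real_
  expect_error(impute_and_pool(all_na, m = 5, fit_fun), "no observed costs")
})

test_that("pooled estimates track the complete-data estimate under MAR", {
  hits <- 0L
  reps <- 20
  for (r in seq_len(reps)) {
    complete <- quick_sim(2500, seed = 900 + r, missing_rate = 0)
    missing <- quick_sim(2500, seed = 900 + r, missing_rate = 0.35)
    truth_fit <- fit_iv_cost(complete)
    z <- prs_of(missing)
    pooled <- impute_and_pool(missing$cohort, m = 10, function(ch) {
      fit_2sls(ch$annual_cost, ch$cancer, z, mr_covariates(ch),
               outcome_label = "annual_cost", exposure_label = "cancer")
    }, seed = r)
    if (abs(pooled$beta - truth_fit$beta) < 2 * pooled$se) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
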