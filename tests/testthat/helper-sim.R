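# Shared fixtures built in code: small cohorts and convenience fitters.

quick_sim <- function(n = 2000, seed = 1, ...) {
  generate_cohort(cohort_params(n_individuals = n, seed = seed, ...))
}

prs_of <- function(sim, ...) {
  suppressMessages(build_prs(sim$dosages, sim$weights, ...))
}

fit_iv_cost <- function(sim, prs = prs_of(sim)) {
  fit_2sls(sim$cohort$annual_cost, sim$cohort$cancer, prs,
           mr_covariates(sim$cohort),
           outcome_label = "annual_cost", exposure_label = "cancer")
}

fit_ols_cost <- function(sim) {
  fit_ols(sim$cohort$annual_cost, sim$cohort$cancer,
          mr_covariates(sim$cohort),
          outcome_label = "annual_cost", exposure_label = "cancer")
}

# generator settings for estimator-validation experiments: boundary
# truncation/clamping made negligible so the linear estimand is exact
recovery_params <- function(n, seed, ...) {
  cohort_params(n_individuals = n, seed = seed,
                beta_cost = 800, beta_qaly = -0.05,
                cost_baseline = 1500, qaly_noise_sd = 0.05,
                missing_rate = 0, ...)
}
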