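#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates the ground-truth parameters of the data-generating
#' process used throughout the package: a liability-threshold model for a
#' binary cancer exposure driven by independent biallelic variants, a latent
#' confounder that jointly shifts cancer liability, annual health care costs
#' and annual QALYs, right-skewed cost noise, and centre-driven
#' missing-at-random cost missingness.
#'
#' @param n_individuals number of individuals to simulate.
#' @param n_variants number of independent variants contributing to liability.
#' @param allele_freqs per-variant effect-allele frequencies, strictly inside
#'   (0, 1). Default: an even grid from 0.1 to 0.5.
#' @param true_log_or per-variant true log-odds effects on cancer liability.
#'   Because liability noise is logistic, these are genuine log-odds ratios.
#'   Default 0.25 per variant, giving a strong polygenic instrument.
#' @param prevalence target cancer prevalence in (0, 1), imposed through the
#'   empirical liability quantile within the eligible sample.
#' @param beta_cost true causal effect of cancer on annual cost (GBP/year).
#' @param beta_qaly true causal effect of cancer on the annual QALY fraction
#'   (typically negative; entered into the model as `-abs(beta_qaly)`).
#' @param confounder_effects length-3 numeric (liability, cost, qaly): effects
#'   of a standard-normal latent confounder on the three equations.
#' @param cost_baseline baseline annual cost (GBP/year) at the midpoint age.
#' @param qaly_baseline baseline annual QALY fraction at age 55.
#' @param cost_noise_sd standard deviation of the right-skewed (lognormal)
#'   cost noise, GBP/year.
#' @param qaly_noise_sd standard deviation of the Gaussian QALY noise
#'   (fraction of a QALY).
#' @param age_range length-2 numeric, uniform age range at recruitment (years).
#' @param sex_ratio probability an individual is male.
#' @param n_centres number of recruitment centres.
#' @param n_pcs number of genetic principal components (standard normal).
#' @param missing_rate average proportion of annual costs set missing, in
#'   \[0, 1); realised missingness probability varies by centre only.
#' @param sex_specific one of "none", "male", "female": if not "none", only
#'   that sex can express the cancer (the other sex always has status 0), and
#'   the prevalence target applies within the eligible sex.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#'
#' @return an object of class `cohort_params` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_individuals,
                          n_variants = 10,
                          allele_freqs = NULL,
                          true_log_or = NULL,
                          prevalence = 0.05,
                          beta_cost = 800,
                          beta_qaly = -0.05,
                          confounder_effects = c(liability = 0.5, cost = 200,
                                                 qaly = -0.05),
                          cost_baseline = 650,
                          qaly_baseline = 0.78,
                          cost_noise_sd = 1200,
                          qaly_noise_sd = 0.12,
                          age_range = c(40, 70),
                          sex_ratio = 0.46,
                          n_centres = 5,
                          n_pcs = 10,
                          missing_rate = 0.3,
                          sex_specific = c("none", "male", "female"),
                          seed = 1L) {
  sex_specific <- match.arg(sex_specific)
  if (is.null(allele_freqs)) {
    allele_freqs <- seq(0.1, 0.5, length.out = n_variants)
  }
  if (is.null(true_log_or)) true_log_or <- rep(0.25, n_variants)

  p <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    allele_freqs = as.numeric(allele_freqs),
    true_log_or = as.numeric(true_log_or),
    prevalence = prevalence,
    beta_cost = beta_cost,
    beta_qaly = beta_qaly,
    confounder_effects = stats::setNames(as.numeric(confounder_effects),
                                         c("liability", "cost", "qaly")),
    cost_baseline = cost_baseline,
    qaly_baseline = qaly_baseline,
    cost_noise_sd = cost_noise_sd,
    qaly_noise_sd = qaly_noise_sd,
    age_range = as.numeric(age_range),
    sex_ratio = sex_ratio,
    n_centres = as.integer(n_centres),
    n_pcs = as.integer(n_pcs),
    missing_rate = missing_rate,
    sex_specific = sex_specific,
    seed = as.integer(seed)
  ), class = "cohort_params")
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  fail <- function(param, msg) {
    stop(sprintf("invalid generator parameter `%s`: %s", param, msg),
         call. = FALSE)
  }
  if (is.na(p$n_individuals) || p$n_individuals < 1) {
    fail("n_individuals", "must be a positive count")
  }
  if (p$n_variants < 1) fail("n_variants", "must be a positive count")
  if (length(p$allele_freqs) != p$n_variants) {
    fail("allele_freqs", "length must equal n_variants")
  }
  if (length(p$true_log_or) != p$n_variants) {
    fail("true_log_or", "length must equal n_variants")
  }
  if (any(p$allele_freqs <= 0 | p$allele_freqs >= 1)) {
    fail("allele_freqs", "must be strictly inside (0, 1)")
  }
  if (p$prevalence <= 0 || p$prevalence >= 1) {
    fail("prevalence", "must be in (0, 1)")
  }
  if (p$missing_rate < 0 || p$missing_rate >= 1) {
    fail("missing_rate", "must be in [0, 1)")
  }
  if (p$sex_ratio <= 0 || p$sex_ratio >= 1) {
    fail("sex_ratio", "must be in (0, 1)")
  }
  if (length(p$age_range) != 2 || diff(p$age_range) <= 0) {
    fail("age_range", "must be an increasing pair of ages")
  }
  if (p$cost_noise_sd < 0) fail("cost_noise_sd", "must be non-negative")
  if (p$qaly_noise_sd < 0) fail("qaly_noise_sd", "must be non-negative")
  if (p$n_centres < 1) fail("n_centres", "must be a positive count")
  if (p$n_pcs < 0) fail("n_pcs", "must be a non-negative count")
  invisible(p)
}

# Right-skewed, median-zero cost noise: a lognormal anchored at its median.
# Anchoring at the median (offset GBP 400) rather than the mean keeps the
# additive structural cost model exact up to a constant shift while bounding
# the noise below at -offset, so truncation of costs at zero is rare and the
# linear estimand is essentially undistorted.
rcost_noise <- function(n, sd, offset = 400) {
  if (sd == 0) return(numeric(n))
  r <- sd / offset
  t <- (1 + sqrt(1 + 4 * r^2)) / 2   # solves t(t-1) = r^2, t = exp(s^2)
  s <- sqrt(log(t))
  stats::rlnorm(n, meanlog = log(offset), sdlog = s) - offset
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates genotype dosages, a GWAS-style weight table, covariates, a
#' binary cancer status from a liability-threshold model, and annual cost and
#' QALY outcomes, so that every downstream estimator in the package can be
#' validated against known parameters.
#'
#' The liability for individual *i* is
#' `sum_j dosage_ij * true_log_or_j + c_liab * U_i + logistic noise`,
#' with `U_i ~ N(0, 1)` the latent confounder; cancer status is 1 when the
#' liability exceeds the empirical within-sample quantile that yields the
#' target prevalence (among the eligible sex when the cancer is sex-specific).
#' Annual costs are a linear predictor (baseline in age and sex, plus the
#' causal cancer effect and the confounder) plus right-skewed lognormal noise,
#' truncated at zero; annual QALYs are a linear predictor plus Gaussian noise,
#' clamped to \[0, 1\]. A fraction `missing_rate` of costs is set missing with
#' probability depending on recruitment centre only (missing at random given
#' covariates). The weight table reports noisy GWAS estimates of the true
#' per-variant log-odds ratios, emulating a two-sample design.
#'
#' @param params a [cohort_params()] object.
#' @return an object of class `mr_sim`: a list with elements
#'   * `cohort`: data frame (id, age, sex, centre, pc1..pcK, cancer,
#'     annual_cost (NA where missing), annual_qaly, followup, cost_missing);
#'   * `dosages`: individuals x variants numeric matrix in \[0, 2\] with an
#'     `alleles` attribute recording the counted allele per variant;
#'   * `weights`: GWAS weight table (variant, effect_allele, other_allele,
#'     beta, se);
#'   * `truth`: list of all true parameters, the realised prevalence, the
#'     liability threshold, per-centre missingness rates, and any pleiotropy
#'     injections.
#' @examples
#' sim <- generate_cohort(cohort_params(n_individuals = 500, seed = 7))
#' mean(sim$cohort$cancer)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  with_rng(params$seed, {
    n <- params$n_individuals
    J <- params$n_variants

    variant_ids <- sprintf("rs%05d", seq_len(J))
    bases <- c("A", "C", "G", "T")
    effect_allele <- sample(bases, J, replace = TRUE)
    other_allele <- vapply(effect_allele, function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))

    dosages <- matrix(
      vapply(params$allele_freqs, function(af) stats::rbinom(n, 2L, af),
             numeric(n)),
      nrow = n, ncol = J)
    dimnames(dosages) <- list(NULL, variant_ids)
    attr(dosages, "alleles") <- data.frame(
      variant = variant_ids,
      effect_allele = effect_allele,
      other_allele = other_allele,
      stringsAsFactors = FALSE
    )

    # noisy external GWAS estimates of the true per-variant effects
    gwas_se <- stats::runif(J, 0.02, 0.05)
    gwas_beta <- params$true_log_or + stats::rnorm(J, 0, gwas_se)
    weights <- data.frame(
      variant = variant_ids,
      effect_allele = effect_allele,
      other_allele = other_allele,
      beta = gwas_beta,
      se = gwas_se,
      stringsAsFactors = FALSE
    )

    age <- stats::runif(n, params$age_range[1], params$age_range[2])
    sex <- factor(ifelse(stats::runif(n) < params$sex_ratio, "male", "female"),
                  levels = c("female", "male"))
    centre <- sample.int(params$n_centres, n, replace = TRUE)
    pcs <- matrix(stats::rnorm(n * params$n_pcs), n, params$n_pcs)
    colnames(pcs) <- paste0("pc", seq_len(max(params$n_pcs, 0)))[seq_len(params$n_pcs)]

    U <- stats::rnorm(n)
    ce <- params$confounder_effects
    liability <- as.numeric(dosages %*% params$true_log_or) +
      ce[["liability"]] * U + stats::rlogis(n)

    eligible <- switch(params$sex_specific,
                       none = rep(TRUE, n),
                       male = sex == "male",
                       female = sex == "female")
    if (!any(eligible)) {
      stop("invalid generator parameter `sex_specific`: no eligible ",
           "individuals of the required sex", call. = FALSE)
    }
    threshold <- stats::quantile(liability[eligible], 1 - params$prevalence,
                                 names = FALSE)
    cancer <- as.integer(eligible & liability > threshold)
    n_cases_elig <- sum(cancer)
    if (n_cases_elig == 0 || n_cases_elig == sum(eligible)) {
      stop("invalid generator parameter `prevalence`: liability threshold is ",
           "degenerate (all-0 or all-1 cancer status)", call. = FALSE)
    }

    age_mid <- mean(params$age_range)
    cost_pred <- params$cost_baseline + 6 * (age - age_mid) +
      30 * (sex == "male") + params$beta_cost * cancer + ce[["cost"]] * U
    annual_cost <- pmax(0, cost_pred + rcost_noise(n, params$cost_noise_sd))

    qaly_pred <- params$qaly_baseline - 0.004 * (age - 55) -
      abs(params$beta_qaly) * cancer + ce[["qaly"]] * U
    annual_qaly <- pmin(1, pmax(0, qaly_pred +
                                  stats::rnorm(n, 0, params$qaly_noise_sd)))

    followup <- pmax(0.5, stats::rnorm(n, 8.1, 0.8))

    # centre-driven MAR missingness: rates proportional to centre index,
    # averaging to missing_rate over centres, capped below 1
    centre_rates <- pmin(0.95, params$missing_rate * 2 *
                           seq_len(params$n_centres) / (params$n_centres + 1))
    cost_missing <- stats::runif(n) < centre_rates[centre]
    annual_cost[cost_missing] <- NA_real_

    cohort <- data.frame(
      id = sprintf("id%06d", seq_len(n)),
      age = age,
      sex = sex,
      centre = centre,
      pcs,
      cancer = cancer,
      annual_cost = annual_cost,
      annual_qaly = annual_qaly,
      followup = followup,
      cost_missing = cost_missing,
      stringsAsFactors = FALSE
    )

    truth <- list(
      params = unclass(params),
      realised_prevalence = mean(cancer[eligible]),
      liability_threshold = threshold,
      centre_missing_rates = centre_rates,
      pleiotropy = list()
    )

    structure(list(cohort = cohort, dosages = dosages, weights = weights,
                   truth = truth),
              class = "mr_sim")
  })
}

#' @export
print.mr_sim <- function(x, ...) {
  cat("Synthetic MR cohort\n")
  cat(sprintf("  individuals: %d   variants: %d\n",
              nrow(x$cohort), ncol(x$dosages)))
  cat(sprintf("  realised prevalence: %.4f (target %.4f%s)\n",
              x$truth$realised_prevalence, x$truth$params$prevalence,
              if (x$truth$params$sex_specific != "none")
                paste0(" among ", x$truth$params$sex_specific, "s") else ""))
  cat(sprintf("  missing annual costs: %d (%.1f%%)\n",
              sum(x$cohort$cost_missing),
              100 * mean(x$cohort$cost_missing)))
  if (length(x$truth$pleiotropy)) {
    cat(sprintf("  pleiotropy injections: %d\n", length(x$truth$pleiotropy)))
  }
  invisible(x)
}

#' Inject horizontal pleiotropy into a simulated cohort
#'
#' Adds a direct (non-exposure-mediated) per-allele effect of selected
#' variants on annual cost, violating the exclusion restriction for those
#' variants. Used to probe heterogeneity-based pleiotropy diagnostics.
#'
#' @param sim an `mr_sim` object from [generate_cohort()].
#' @param variants character vector of variant ids receiving a direct effect;
#'   may be empty (no-op).
#' @param direct_effect GBP/year added to annual cost per effect allele
#'   carried at each listed variant.
#' @return the modified `mr_sim` object; the injection is recorded in
#'   `sim$truth$pleiotropy`. Missing costs stay missing.
#' @export
inject_pleiotropy <- function(sim, variants, direct_effect) {
  stopifnot(inherits(sim, "mr_sim"), is.numeric(direct_effect),
            length(direct_effect) == 1)
  unknown <- setdiff(variants, colnames(sim$dosages))
  if (length(unknown)) {
    stop("unknown variant id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(variants) == 0 || direct_effect == 0) return(sim)
  extra <- rowSums(sim$dosages[, variants, drop = FALSE]) * direct_effect
  sim$cohort$annual_cost <- sim$cohort$annual_cost + extra
  sim$truth$pleiotropy <- c(sim$truth$pleiotropy,
                            list(list(variants = variants,
                                      direct_effect = direct_effect,
                                      outcome = "annual_cost")))
  sim
}
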