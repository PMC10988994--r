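#' MR/OLS effect estimate container
#'
#' Light S3 container for a single exposure-outcome effect estimate with a
#' heteroskedasticity-robust standard error, used by both the 2SLS Mendelian
#' randomization and multivariable OLS fits.
#'
#' @param beta point estimate (outcome units per unit exposure).
#' @param se robust standard error.
#' @param n number of observations used.
#' @param first_stage_f first-stage robust F (2SLS only, else `NA`).
#' @param outcome_label,exposure_label character labels.
#' @param method `"2sls"` or `"ols"`.
#' @return object of class `mr_estimate` with fields beta, se,
#'   `ci95 = beta +/- 1.96 * se`, first_stage_f, n, labels and method.
#' @export
mr_estimate <- function(beta, se, n, first_stage_f = NA_real_,
                        outcome_label = "outcome",
                        exposure_label = "exposure",
                        method = c("2sls", "ols")) {
  method <- match.arg(method)
  # se = 0 only in degenerate perfect-fit cases (e.g. outcome == exposure)
  if (!is.finite(se) || se < 0) stop("standard error must be non-negative")
  structure(list(
    beta = as.numeric(beta),
    se = as.numeric(se),
    ci95 = c(lower = beta - Z95 * se, upper = beta + Z95 * se),
    first_stage_f = if (method == "2sls") as.numeric(first_stage_f) else NA_real_,
    n = as.integer(n),
    outcome_label = outcome_label,
    exposure_label = exposure_label,
    method = method
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: %s on %s\n",
              toupper(x$method), x$exposure_label, x$outcome_label))
  cat(sprintf("  beta %.4g (robust SE %.4g), 95%% CI [%.4g, %.4g], n = %d\n",
              x$beta, x$se, x$ci95[1], x$ci95[2], x$n))
  if (x$method == "2sls") {
    cat(sprintf("  first-stage robust F = %.1f\n", x$first_stage_f))
  }
  invisible(x)
}

# rows usable by a fit: complete in outcome, exposure, instrument, covariates
complete_rows <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  ok <- Reduce(`&`, lapply(parts, function(p) {
    if (is.matrix(p)) stats::complete.cases(p) else !is.na(p)
  }))
  ok
}

first_stage_f_robust <- function(exposure, instrument, covariates) {
  df <- if (is.null(covariates)) {
    data.frame(.z = instrument)
  } else {
    data.frame(.z = instrument, covariates, check.names = TRUE)
  }
  fs <- stats::lm(exposure ~ ., data = df)
  if (anyNA(stats::coef(fs))) {
    stop("first-stage design matrix is rank deficient", call. = FALSE)
  }
  V <- sandwich::vcovHC(fs, type = "HC1")
  b <- stats::coef(fs)[[".z"]]
  as.numeric(b^2 / V[".z", ".z"])
}

#' Just-identified two-stage least squares with a polygenic instrument
#'
#' Estimates the causal effect of a binary exposure on an outcome using a
#' single instrument (a polygenic risk score), via the closed-form
#' just-identified IV estimator `beta = (Z'X)^{-1} Z'y` with `Z = [1, z, C]`
#' and `X = [1, d, C]`. This equals running stage 1 (exposure on instrument
#' plus covariates) and stage 2 (outcome on fitted exposure plus covariates).
#' The standard error is the heteroskedasticity-robust (HC1) IV sandwich
#' using residuals formed with the *observed* exposure,
#' `(Z'X)^{-1} Z' diag(e^2) Z (X'Z)^{-1} * n/(n - k)`. The first-stage
#' robust F for the instrument is reported as the instrument-strength
#' diagnostic. Rows with any missing value are dropped.
#'
#' The estimand is the additive structural mean: the average change in the
#' outcome caused by having versus not having the exposure, assuming a
#' constant effect across the population.
#'
#' @param outcome numeric outcome vector (GBP/year, or percentage points of a
#'   QALY per year after [scale_qaly()]).
#' @param exposure binary 0/1 exposure vector.
#' @param instrument numeric instrument vector (e.g. from [build_prs()]).
#' @param covariates optional numeric covariate matrix (no intercept column),
#'   e.g. from [mr_covariates()].
#' @param outcome_label,exposure_label labels carried into the result.
#' @return an [mr_estimate()] with `method = "2sls"`.
#' @examples
#' sim <- generate_cohort(cohort_params(2000, seed = 3))
#' z <- build_prs(sim$dosages, sim$weights)
#' fit_2sls(sim$cohort$annual_cost, sim$cohort$cancer, z,
#'          mr_covariates(sim$cohort))
#' @export
fit_2sls <- function(outcome, exposure, instrument, covariates = NULL,
                     outcome_label = "outcome", exposure_label = "exposure") {
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  instrument <- as.numeric(instrument)
  n_in <- length(outcome)
  stopifnot(length(exposure) == n_in, length(instrument) == n_in)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n_in)
  }
  ok <- complete_rows(outcome, exposure, instrument, covariates)
  y <- outcome[ok]
  d <- exposure[ok]
  z <- instrument[ok]
  C <- if (!is.null(covariates)) covariates[ok, , drop = FALSE] else NULL
  n <- length(y)
  if (n < 3) stop("too few complete observations")
  if (stats::var(z) <= 0) stop("instrument has zero variance")

  X <- cbind(`(Intercept)` = 1, exposure = d, C)
  Z <- cbind(1, z, C)
  k <- ncol(X)
  ZtX <- crossprod(Z, X)
  if (qr(ZtX)$rank < k) stop("design matrix is rank deficient")
  A <- solve(ZtX)
  beta_vec <- A %*% crossprod(Z, y)
  e <- as.numeric(y - X %*% beta_vec)
  meat <- crossprod(Z * e)
  V <- A %*% meat %*% t(A) * n / (n - k)
  se <- sqrt(pmax(diag(V), 0))[2]
  if (!is.finite(se)) stop("IV sandwich produced a non-finite SE")

  f <- first_stage_f_robust(d, z, C)
  mr_estimate(beta = beta_vec[2], se = se, n = n, first_stage_f = f,
              outcome_label = outcome_label, exposure_label = exposure_label,
              method = "2sls")
}

#' Multivariable OLS effect of an exposure on an outcome
#'
#' Conventional multivariable linear regression of the outcome on the
#' exposure and covariates, reporting the exposure coefficient with an HC1
#' heteroskedasticity-robust standard error. The comparator for the 2SLS
#' Mendelian randomization fits in the Hausman endogeneity test.
#'
#' @inheritParams fit_2sls
#' @param exposure numeric exposure vector (binary for the main analysis;
#'   continuous scores are accepted, e.g. in negative-control models).
#' @return an [mr_estimate()] with `method = "ols"`.
#' @export
fit_ols <- function(outcome, exposure, covariates = NULL,
                    outcome_label = "outcome", exposure_label = "exposure") {
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  n_in <- length(outcome)
  stopifnot(length(exposure) == n_in)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n_in)
  }
  ok <- complete_rows(outcome, exposure, covariates)
  y <- outcome[ok]
  d <- exposure[ok]
  C <- if (!is.null(covariates)) covariates[ok, , drop = FALSE] else NULL
  df <- if (is.null(C)) data.frame(.d = d) else
    data.frame(.d = d, C, check.names = TRUE)
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("design matrix is rank deficient")
  V <- sandwich::vcovHC(fit, type = "HC1")
  mr_estimate(beta = stats::coef(fit)[[".d"]], se = sqrt(V[".d", ".d"]),
              n = length(y), outcome_label = outcome_label,
              exposure_label = exposure_label, method = "ols")
}

#' Hausman endogeneity test comparing 2SLS and OLS estimates
#'
#' `statistic = (beta_iv - beta_ols)^2 / (se_iv^2 - se_ols^2)`, referred to a
#' chi-squared distribution with 1 degree of freedom. A small p-value is
#' evidence the instrumented and conventional estimates differ, i.e. that the
#' exposure is endogenous in the OLS fit. The contrast variance estimator is
#' not guaranteed positive in finite samples; when `se_iv^2 - se_ols^2 <= 0`
#' the statistic is clamped to 0 with `p = 1` and a warning.
#'
#' @param iv an [mr_estimate()] with method `"2sls"`.
#' @param ols an [mr_estimate()] with method `"ols"` on the same outcome,
#'   exposure and sample size.
#' @return list of class `hausman_result`: statistic, df (= 1), p_value.
#' @export
hausman_test <- function(iv, ols) {
  stopifnot(inherits(iv, "mr_estimate"), inherits(ols, "mr_estimate"))
  if (iv$method != "2sls" || ols$method != "ols") {
    stop("`iv` must be a 2SLS estimate and `ols` an OLS estimate")
  }
  if (iv$outcome_label != ols$outcome_label ||
      iv$exposure_label != ols$exposure_label || iv$n != ols$n) {
    stop("mismatched estimates: outcome, exposure and n must agree")
  }
  vdiff <- iv$se^2 - ols$se^2
  if (vdiff <= 0) {
    warning("variance difference non-positive; Hausman statistic clamped to 0",
            call. = FALSE)
    stat <- 0
    p <- 1
  } else {
    stat <- (iv$beta - ols$beta)^2 / vdiff
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = 1L, p_value = p),
            class = "hausman_result")
}

#' @export
print.hausman_result <- function(x, ...) {
  cat(sprintf("Hausman endogeneity test: chi-sq(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Build the default analysis covariate matrix from a cohort
#'
#' Age, a male indicator, the genetic principal components, and recruitment
#' centre indicators (one-hot with the first observed level dropped), mirroring
#' the covariate set used for both the MR and multivariable analyses. Unused
#' centre levels (e.g. after stratification) are dropped.
#'
#' @param cohort cohort data frame.
#' @param drop_sex drop the sex indicator (for sex-stratified or sex-specific
#'   analyses).
#' @return numeric matrix, one row per cohort row, no intercept column.
#' @export
mr_covariates <- function(cohort, drop_sex = FALSE) {
  stopifnot(is.data.frame(cohort))
  pcs <- as.matrix(cohort[, grep("^pc[0-9]+$", names(cohort)), drop = FALSE])
  M <- cbind(age = cohort$age)
  if (!drop_sex) M <- cbind(M, sex_male = as.numeric(cohort$sex == "male"))
  if (ncol(pcs)) M <- cbind(M, pcs)
  centre <- factor(cohort$centre)
  if (nlevels(centre) > 1) {
    cm <- stats::model.matrix(~centre)[, -1, drop = FALSE]
    M <- cbind(M, cm)
  }
  M
}

#' Rescale QALY fractions to percentage points
#'
#' Annual QALY fractions are multiplied by 100 before estimation so that
#' effect estimates read as the percentage of a QALY changed per year by
#' having versus not having the exposure.
#'
#' @param outcome numeric vector of QALY fractions.
#' @return the vector times 100, with a `units` attribute
#'   `"% of a QALY per year"`.
#' @export
scale_qaly <- function(outcome) {
  stopifnot(is.numeric(outcome))
  structure(outcome * 100, units = "% of a QALY per year")
}

outcome_values <- function(cohort, outcome) {
  y <- cohort[[outcome]]
  if (is.null(y)) stop("unknown outcome column: ", outcome)
  if (outcome == "annual_qaly") y <- scale_qaly(y)
  y
}

#' Stratified 2SLS Mendelian randomization
#'
#' Reruns [fit_2sls()] within strata defined by sex, by age bands, or by an
#' arbitrary labelling. Sex is dropped from the covariates inside sex strata
#' (and the centre indicators are rebuilt per stratum). Strata that fail the
#' preconditions (missing exposure class, degenerate instrument, or a fit
#' error) are reported as skipped with their reason, never silently dropped.
#'
#' @param cohort,dosages,weights components of an `mr_sim` bundle (or
#'   equivalents read from disk).
#' @param variable `"sex"`, `"age_band"`, or `"custom"`.
#' @param breaks for `age_band`: interior age cutpoints (default `c(50, 60)`
#'   giving bands `<50`, `50-59`, `60+`).
#' @param custom for `variable = "custom"`: a factor/vector of stratum labels,
#'   one per cohort row.
#' @param outcome outcome column name (`annual_qaly` is scaled to percentage
#'   points automatically).
#' @param scheme PRS weighting scheme passed to [build_prs()].
#' @return list with `estimates` (named list of [mr_estimate()]) and
#'   `skipped` (named character vector of reasons).
#' @export
stratified_mr <- function(cohort, dosages, weights,
                          variable = c("sex", "age_band", "custom"),
                          breaks = c(50, 60), custom = NULL,
                          outcome = "annual_cost", scheme = "beta") {
  variable <- match.arg(variable)
  prs <- build_prs(dosages, weights, scheme = scheme)
  y <- outcome_values(cohort, outcome)

  strata <- switch(variable,
    sex = cohort$sex,
    age_band = {
      labs <- c(paste0("<", breaks[1]),
                if (length(breaks) > 1) {
                  paste0(utils::head(breaks, -1), "-", breaks[-1] - 1)
                },
                paste0(utils::tail(breaks, 1), "+"))
      cut(cohort$age, c(-Inf, breaks, Inf), labels = labs, right = FALSE)
    },
    custom = {
      if (is.null(custom)) stop("`custom` labels required")
      if (length(custom) != nrow(cohort)) {
        stop("`custom` must have one label per cohort row")
      }
      factor(custom)
    })

  estimates <- list()
  skipped <- character()
  for (lev in levels(factor(strata))) {
    idx <- which(strata == lev)
    sub <- cohort[idx, , drop = FALSE]
    reason <- NULL
    if (length(unique(sub$cancer)) < 2) {
      reason <- "only one exposure class present"
    } else if (stats::var(prs[idx]) == 0) {
      reason <- "instrument has zero variance"
    }
    if (is.null(reason)) {
      est <- tryCatch(
        fit_2sls(y[idx], sub$cancer, prs[idx],
                 mr_covariates(sub, drop_sex = variable == "sex"),
                 outcome_label = outcome, exposure_label = "cancer"),
        error = function(e) conditionMessage(e)
      )
      if (inherits(est, "mr_estimate")) estimates[[lev]] <- est
      else reason <- est
    }
    if (!is.null(reason)) skipped[lev] <- reason
  }
  list(estimates = estimates, skipped = skipped)
}

#' Negative-control regression of outcomes on a cross-sex cancer score
#'
#' For a sex-specific cancer, the polygenic score should carry no signal in
#' the sex that cannot express the cancer; regressing the outcomes on that
#' score among the control sex (with age, principal components and centre as
#' covariates, sex dropped) should therefore be consistent with the null if
#' the score acts only through the cancer.
#'
#' @param cohort cohort data frame.
#' @param prs polygenic score vector aligned with the cohort rows (the score
#'   of the *other* sex's cancer).
#' @param control_sex `"male"` or `"female"`: the sex that cannot express the
#'   cancer. Requesting a sex in which cases occur is an error (it would not
#'   be a negative control).
#' @param outcomes outcome column names.
#' @return named list of [mr_estimate()] (method `"ols"`), one per outcome;
#'   betas are per unit of the score.
#' @export
negative_control <- function(cohort, prs,
                             control_sex = c("female", "male"),
                             outcomes = c("annual_cost", "annual_qaly")) {
  control_sex <- match.arg(control_sex)
  stopifnot(length(prs) == nrow(cohort))
  keep <- cohort$sex == control_sex
  if (!any(keep)) {
    stop("no individuals of the requested control sex in the cohort")
  }
  sub <- cohort[keep, , drop = FALSE]
  if (any(sub$cancer == 1)) {
    stop("cancer cases occur in the requested control sex; ",
         "this is not a negative control")
  }
  C <- mr_covariates(sub, drop_sex = TRUE)
  out <- lapply(outcomes, function(o) {
    fit_ols(outcome_values(sub, o), prs[keep], C,
            outcome_label = o, exposure_label = "cross_sex_prs")
  })
  stats::setNames(out, outcomes)
}

#' Regression imputation of missing costs with Rubin's-rules pooling
#'
#' Each of `m` completed data sets replaces missing annual costs with the
#' prediction of a linear regression on the analysis covariates plus the
#' exposure (fitted to the observed costs), plus a residual resampled with
#' replacement from that regression. The supplied `fit` function is applied
#' to every completed cohort and the resulting estimates pooled by Rubin's
#' rules: pooled beta is the mean of the per-imputation betas; pooled
#' variance is `W + (1 + 1/m) B`, where `W` is the mean within-imputation
#' variance and `B` the between-imputation variance of the betas.
#'
#' With no missing costs the single fit is returned unchanged.
#'
#' @param cohort cohort data frame with `annual_cost` (NA where missing).
#' @param m number of imputations (>= 2).
#' @param fit function taking a completed cohort data frame and returning an
#'   [mr_estimate()].
#' @param exposure exposure column used in the imputation model.
#' @param seed optional integer seed for the residual resampling.
#' @return pooled [mr_estimate()]; attributes `m`, `within_variance` and
#'   `between_variance` record the pooling components.
#' @export
impute_and_pool <- function(cohort, m, fit, exposure = "cancer", seed = NULL) {
  miss <- is.na(cohort$annual_cost)
  if (!any(miss)) return(fit(cohort))
  if (m < 2) stop("`m` must be at least 2")
  if (all(miss)) stop("no observed costs to fit the imputation model")

  X <- cbind(mr_covariates(cohort), exposure = cohort[[exposure]])
  obs <- which(!miss)
  idf <- data.frame(.y = cohort$annual_cost, X, check.names = TRUE)
  imodel <- stats::lm(.y ~ ., data = idf[obs, , drop = FALSE])
  pred_miss <- stats::predict(imodel, newdata = idf[miss, , drop = FALSE])
  res <- stats::residuals(imodel)

  run <- function() {
    ests <- vector("list", m)
    for (k in seq_len(m)) {
      completed <- cohort
      completed$annual_cost[miss] <- pred_miss +
        sample(res, sum(miss), replace = TRUE)
      ests[[k]] <- fit(completed)
    }
    ests
  }
  ests <- if (is.null(seed)) run() else with_rng(seed, run())

  betas <- vapply(ests, `[[`, numeric(1), "beta")
  ses <- vapply(ests, `[[`, numeric(1), "se")
  W <- mean(ses^2)
  B <- stats::var(betas)
  pooled <- mr_estimate(
    beta = mean(betas), se = sqrt(W + (1 + 1 / m) * B), n = ests[[1]]$n,
    first_stage_f = mean(vapply(ests, `[[`, numeric(1), "first_stage_f")),
    outcome_label = ests[[1]]$outcome_label,
    exposure_label = ests[[1]]$exposure_label,
    method = ests[[1]]$method
  )
  attr(pooled, "m") <- m
  attr(pooled, "within_variance") <- W
  attr(pooled, "between_variance") <- B
  pooled
}

#' Tidy one or more effect estimates into a results table
#'
#' @param ... [mr_estimate()] objects or (possibly nested) lists of them.
#' @param stratum optional single stratum label recycled across rows.
#' @return data frame with one row per estimate: exposure, outcome, method,
#'   stratum, beta, se, ci_lower, ci_upper, first_stage_f, n.
#' @export
mr_results_table <- function(..., stratum = "all") {
  flatten <- function(x) {
    if (inherits(x, "mr_estimate")) return(list(x))
    if (is.list(x)) return(do.call(c, lapply(x, flatten)))
    stop("not an mr_estimate")
  }
  ests <- flatten(list(...))
  do.call(rbind, lapply(ests, function(e) {
    data.frame(exposure = e$exposure_label, outcome = e$outcome_label,
               method = e$method, stratum = stratum, beta = e$beta,
               se = e$se, ci_lower = e$ci95[[1]], ci_upper = e$ci95[[2]],
               first_stage_f = e$first_stage_f, n = e$n,
               stringsAsFactors = FALSE)
  }))
}
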