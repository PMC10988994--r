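#' Per-variant Wald ratio estimates (overidentified MR)
#'
#' For each variant, regresses the exposure and the outcome separately on
#' that variant's dosage plus covariates (HC1 robust standard errors) and
#' forms the Wald ratio `beta_outcome / beta_exposure` with first-order
#' delta-method standard error `se_outcome / |beta_exposure|`. Heterogeneity
#' between these per-variant ratios is the diagnostic for exclusion-
#' restriction violations (horizontal pleiotropy).
#'
#' @param exposure binary 0/1 exposure vector.
#' @param outcome numeric outcome vector.
#' @param dosages individuals x variants dosage matrix.
#' @param covariates optional covariate matrix from [mr_covariates()].
#' @return data frame of class `snp_estimates` with one row per usable
#'   variant: variant, beta_exposure, se_exposure, beta_outcome, se_outcome,
#'   wald_ratio, se_ratio. Variants whose exposure association is below
#'   1e-12 in absolute value are excluded with a warning.
#' @export
per_snp_estimates <- function(exposure, outcome, dosages, covariates = NULL) {
  stopifnot(is.matrix(dosages))
  if (ncol(dosages) < 2) stop("at least 2 variants are required")
  exposure <- as.numeric(exposure)
  outcome <- as.numeric(outcome)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  ok <- complete_rows(exposure, outcome, covariates)
  d <- exposure[ok]
  y <- outcome[ok]
  G <- dosages[ok, , drop = FALSE]
  C <- if (!is.null(covariates)) covariates[ok, , drop = FALSE] else NULL

  one <- function(yy, g) {
    df <- if (is.null(C)) data.frame(.g = g) else
      data.frame(.g = g, C, check.names = TRUE)
    fit <- stats::lm(yy ~ ., data = df)
    b <- stats::coef(fit)[[".g"]]
    if (is.na(b)) return(c(0, Inf))  # aliased dosage column: no signal
    V <- sandwich::vcovHC(fit, type = "HC1")
    c(b, sqrt(V[".g", ".g"]))
  }

  rows <- lapply(colnames(G), function(v) {
    ex <- one(d, G[, v])
    ou <- one(y, G[, v])
    data.frame(variant = v,
               beta_exposure = ex[1], se_exposure = ex[2],
               beta_outcome = ou[1], se_outcome = ou[2],
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  tiny <- abs(est$beta_exposure) < 1e-12
  if (any(tiny)) {
    warning("excluding variant(s) with near-zero exposure association: ",
            paste(est$variant[tiny], collapse = ", "), call. = FALSE)
    est <- est[!tiny, , drop = FALSE]
  }
  est$wald_ratio <- est$beta_outcome / est$beta_exposure
  est$se_ratio <- est$se_outcome / abs(est$beta_exposure)
  class(est) <- c("snp_estimates", class(est))
  est
}

#' Inverse-variance-weighted pooling with Cochran's Q
#'
#' Fixed-effect IVW pooling of per-variant Wald ratios: with weights
#' `w_j = 1 / se_j^2`, the pooled estimate is `sum(w r) / sum(w)` with
#' standard error `sum(w)^{-1/2}`, and Cochran's
#' `Q = sum(w (r - pooled)^2)` is referred to chi-squared with
#' `n_snps - 1` degrees of freedom. A small Q p-value indicates
#' heterogeneity between variants, consistent with horizontal pleiotropy.
#'
#' @param estimates either a `snp_estimates` data frame from
#'   [per_snp_estimates()] (columns `wald_ratio`, `se_ratio`), or a numeric
#'   vector of estimates.
#' @param se standard errors, when `estimates` is a numeric vector.
#' @return list of class `ivw_result`: beta_pooled, se_pooled, q_statistic,
#'   q_df (= n_snps - 1), q_pvalue, n_snps.
#' @export
ivw_pool <- function(estimates, se = NULL) {
  if (is.data.frame(estimates)) {
    r <- estimates$wald_ratio
    s <- estimates$se_ratio
  } else {
    r <- as.numeric(estimates)
    s <- as.numeric(se)
  }
  keep <- is.finite(r) & is.finite(s) & s > 0
  r <- r[keep]
  s <- s[keep]
  if (length(r) < 2) stop("at least 2 usable estimates are required")
  w <- 1 / s^2
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  df <- length(r) - 1L
  structure(list(
    beta_pooled = beta,
    se_pooled = 1 / sqrt(sum(w)),
    q_statistic = q,
    q_df = df,
    q_pvalue = stats::pchisq(q, df = df, lower.tail = FALSE),
    n_snps = length(r)
  ), class = "ivw_result")
}

#' @export
print.ivw_result <- function(x, ...) {
  cat(sprintf("IVW pooled estimate over %d variants\n", x$n_snps))
  cat(sprintf("  beta %.4g (SE %.4g)\n", x$beta_pooled, x$se_pooled))
  cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.4g\n",
              x$q_statistic, x$q_df, x$q_pvalue))
  invisible(x)
}

#' MR-Egger intercept test
#'
#' Weighted regression of the per-variant outcome associations on the
#' exposure associations (weights `1 / se_outcome^2`); a non-zero intercept
#' indicates directional pleiotropy. Offered as an optional diagnostic
#' alongside the IVW/Q analysis.
#'
#' @param estimates a `snp_estimates` data frame from [per_snp_estimates()].
#' @return list: intercept, intercept_se, intercept_p, slope, slope_se.
#' @export
egger_regression <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 3)
  fit <- stats::lm(beta_outcome ~ beta_exposure, data = estimates,
                   weights = 1 / estimates$se_outcome^2)
  ct <- summary(fit)$coefficients
  list(intercept = ct[1, 1], intercept_se = ct[1, 2],
       intercept_p = ct[1, 4], slope = ct[2, 1], slope_se = ct[2, 2])
}

#' Long-format table of per-variant and pooled sensitivity results
#'
#' Forest-plot-ready layout: one row per variant plus a pooled IVW row.
#'
#' @param estimates `snp_estimates` data frame.
#' @param pooled `ivw_result` from [ivw_pool()].
#' @return data frame: term, estimate, se, ci_lower, ci_upper.
#' @export
sensitivity_table <- function(estimates, pooled) {
  per <- data.frame(term = estimates$variant,
                    estimate = estimates$wald_ratio,
                    se = estimates$se_ratio,
                    stringsAsFactors = FALSE)
  all <- rbind(per, data.frame(term = "IVW pooled",
                               estimate = pooled$beta_pooled,
                               se = pooled$se_pooled,
                               stringsAsFactors = FALSE))
  all$ci_lower <- all$estimate - Z95 * all$se
  all$ci_upper <- all$estimate + Z95 * all$se
  all
}
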