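#' Case counts within an intervention scenario
#'
#' @param n_cases number of cases (`n`), with `0 < n_cases < n_total`.
#' @param n_total total number of individuals at risk (`N`).
#' @param label scenario name (e.g. `"all"`, `"<50"`, `"50-59"`, `"60+"`).
#' @return list of class `stratum_counts`.
#' @export
stratum_counts <- function(n_cases, n_total, label = "all") {
  if (!(n_cases > 0 && n_cases < n_total)) {
    stop("require 0 < n_cases < n_total")
  }
  structure(list(n_cases = n_cases, n_total = n_total, label = label),
            class = "stratum_counts")
}

#' Proportion of cases and its binomial standard error
#'
#' `p = n/N` with `se = sqrt(p (1 - p) / N)` (the standard binomial standard
#' error of a proportion). Note: the implemented formula takes the square
#' root; the un-rooted variance form sometimes quoted for this quantity
#' yields absurd magnitudes and is not used.
#'
#' @param counts a [stratum_counts()] object.
#' @return list with `proportion` and `se`.
#' @examples
#' proportion_se(stratum_counts(6155, 144032)) # 4.3% of men
#' @export
proportion_se <- function(counts) {
  stopifnot(inherits(counts, "stratum_counts"))
  p <- counts$n_cases / counts$n_total
  list(proportion = p, se = sqrt(p * (1 - p) / counts$n_total))
}

#' Convert an odds ratio into a risk difference at a baseline prevalence
#'
#' Applies an intervention odds ratio `OR` to the baseline odds implied by
#' `n` cases in `N` individuals and back-transforms:
#' `risk difference = n*OR / (N - n + n*OR) - n/N`. Negative when `OR < 1`
#' (the intervention prevents cases).
#'
#' @param counts a [stratum_counts()] object.
#' @param or odds ratio (> 0).
#' @return signed proportion (not a percentage).
#' @examples
#' # 6,155 prostate cancer cases among 144,032 men, OR 0.29 -> about -3.0%
#' or_to_risk_difference(stratum_counts(6155, 144032), 0.29)
#' @export
or_to_risk_difference <- function(counts, or) {
  stopifnot(inherits(counts, "stratum_counts"))
  if (or <= 0) stop("`or` must be positive")
  n <- counts$n_cases
  N <- counts$n_total
  (n * or) / (N - n + n * or) - n / N
}

#' Annualise a monthly drug price
#'
#' @param monthly_price GBP per month (>= 0).
#' @param months months per year (default 12).
#' @return GBP per year (unrounded; round only for display).
#' @examples
#' annualise_drug_cost(39.20) # 470.40, reported as GBP 470
#' @export
annualise_drug_cost <- function(monthly_price, months = 12) {
  if (monthly_price < 0) stop("`monthly_price` must be non-negative")
  monthly_price * months
}

#' Net monetary benefit
#'
#' `NMB = threshold * delta_qaly - delta_cost`; positive means the
#' intervention is cost-effective at that willingness-to-pay threshold.
#'
#' @param delta_cost incremental cost, GBP.
#' @param delta_qaly incremental QALYs (fraction of a QALY, not percentage
#'   points).
#' @param threshold willingness-to-pay, GBP per QALY.
#' @return GBP.
#' @export
nmb <- function(delta_cost, delta_qaly, threshold) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly),
            is.finite(threshold))
  threshold * delta_qaly - delta_cost
}

#' Specification of a preventative drug intervention
#'
#' @param or_point intervention odds ratio on the cancer (> 0).
#' @param or_ci95 length-2 95% CI for the odds ratio (positive, ordered;
#'   bounds may coincide for a degenerate, uncertainty-free run).
#' @param drug_cost_annual GBP per person per year.
#' @param wtp_threshold willingness-to-pay, GBP per QALY.
#' @param n_draws number of Monte-Carlo draws (>= 1).
#' @param seed integer seed for the draws.
#' @param or_scale `"log"` (default; OR uncertainty drawn on the log scale,
#'   keeping draws positive) or `"natural"`.
#' @return list of class `intervention_spec`.
#' @export
intervention_spec <- function(or_point, or_ci95, drug_cost_annual,
                              wtp_threshold = 20000, n_draws = 10000,
                              seed = 1L, or_scale = c("log", "natural")) {
  or_scale <- match.arg(or_scale)
  if (or_point <= 0) stop("`or_point` must be positive")
  if (length(or_ci95) != 2 || any(or_ci95 <= 0) || or_ci95[1] > or_ci95[2]) {
    stop("`or_ci95` must be a positive ordered pair")
  }
  if (n_draws < 1) stop("`n_draws` must be at least 1")
  structure(list(or_point = or_point, or_ci95 = as.numeric(or_ci95),
                 drug_cost_annual = drug_cost_annual,
                 wtp_threshold = wtp_threshold,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 or_scale = or_scale),
            class = "intervention_spec")
}

#' Effect of the cancer on costs and QALYs, with uncertainty
#'
#' The third simulation input: the estimated causal (or multivariable)
#' effect of the cancer on annual cost (GBP/year) and on QALYs (percentage
#' points of a QALY per year, i.e. after the x100 scaling).
#'
#' @param cost_effect point estimate, GBP/year.
#' @param cost_ci95 length-2 95% CI for the cost effect (ordered).
#' @param qaly_effect point estimate, percentage points of a QALY per year
#'   (negative when the cancer reduces QALYs).
#' @param qaly_ci95 length-2 95% CI for the QALY effect (ordered).
#' @param source `"mendelian_randomization"` or `"multivariable"`.
#' @return list of class `effect_input`.
#' @export
effect_input <- function(cost_effect, cost_ci95, qaly_effect, qaly_ci95,
                         source = c("mendelian_randomization",
                                    "multivariable")) {
  source <- match.arg(source)
  if (length(cost_ci95) != 2 || cost_ci95[1] > cost_ci95[2]) {
    stop("`cost_ci95` must be an ordered pair")
  }
  if (length(qaly_ci95) != 2 || qaly_ci95[1] > qaly_ci95[2]) {
    stop("`qaly_ci95` must be an ordered pair")
  }
  structure(list(cost_effect = cost_effect, cost_ci95 = as.numeric(cost_ci95),
                 qaly_effect = qaly_effect, qaly_ci95 = as.numeric(qaly_ci95),
                 source = source),
            class = "effect_input")
}

se_from_ci <- function(ci) (ci[2] - ci[1]) / (2 * Z95)

# normal draws truncated to an open interval by redraw, with a clamp
# fallback for pathological parameter combinations
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x <= lower | x >= upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower + 1e-12), upper - 1e-12)
}

#' Monte-Carlo cost-effectiveness simulation of a preventative intervention
#'
#' Propagates uncertainty in three quantities through `n_draws` Monte-Carlo
#' draws: the intervention odds ratio (drawn on the log scale by default,
#' with SE recovered from the CI width), the baseline case proportion
#' (normal about `n/N` with binomial SE, truncated to (0, 1) and rescaled to
#' counts), and the cost and QALY effects of the cancer (normal about the
#' point estimates with SEs from the CI widths; drawn independently). Per
#' draw, the odds ratio and counts give a risk difference `RD`, and
#'
#' * `delta cost = drug_cost_annual + RD * cost_effect` (GBP/person/year),
#' * `delta QALY = RD * qaly_effect` (percentage points/person/year;
#'   positive when preventing the cancer raises QALYs),
#' * `NMB = (delta QALY / 100) * wtp_threshold - delta cost`.
#'
#' Medians are reported as point estimates with the 2.5 and 97.5 percentiles
#' as 95% intervals, against a do-nothing comparator. The break-even price
#' `drug_cost_annual + median(NMB)` is the annual drug price at which the
#' median NMB crosses zero (NMB draws translate one-for-one with price); it
#' is verified by re-running the simulation at that price with the same
#' seed.
#'
#' @param spec an [intervention_spec()].
#' @param effects an [effect_input()].
#' @param counts a [stratum_counts()].
#' @param keep_draws keep the per-draw matrix in the result (for
#'   diagnostics).
#' @param .verify_breakeven internal guard against infinite recursion when
#'   re-running at the break-even price.
#' @return object of class `cea_result`: `summary` data frame (quantity,
#'   median, ci_lower, ci_upper), `breakeven_price`,
#'   `breakeven_verified_nmb` (median NMB when re-run at that price),
#'   scenario metadata, and optionally `draws`.
#' @export
run_intervention_sim <- function(spec, effects, counts, keep_draws = FALSE,
                                 .verify_breakeven = TRUE) {
  stopifnot(inherits(spec, "intervention_spec"),
            inherits(effects, "effect_input"),
            inherits(counts, "stratum_counts"))
  ps <- proportion_se(counts)
  N <- counts$n_total

  draws <- with_rng(spec$seed, {
    nd <- spec$n_draws
    or_d <- if (spec$or_scale == "log") {
      se_lor <- se_from_ci(log(spec$or_ci95))
      exp(stats::rnorm(nd, log(spec$or_point), se_lor))
    } else {
      rnorm_trunc(nd, spec$or_point, se_from_ci(spec$or_ci95), 0, Inf)
    }
    p_d <- rnorm_trunc(nd, ps$proportion, ps$se, 0, 1)
    n_d <- p_d * N
    rd <- (n_d * or_d) / (N - n_d + n_d * or_d) - n_d / N
    cost_eff <- stats::rnorm(nd, effects$cost_effect,
                             se_from_ci(effects$cost_ci95))
    qaly_eff <- stats::rnorm(nd, effects$qaly_effect,
                             se_from_ci(effects$qaly_ci95))
    delta_cost <- spec$drug_cost_annual + rd * cost_eff
    delta_qaly <- rd * qaly_eff
    nmb_d <- nmb(delta_cost, delta_qaly / 100, spec$wtp_threshold)
    cbind(risk_difference = rd, delta_cost = delta_cost,
          delta_qaly = delta_qaly, nmb = nmb_d)
  })

  if (!all(is.finite(draws))) stop("non-finite draws encountered")

  qs <- function(x) {
    c(median = stats::median(x),
      stats::quantile(x, c(0.025, 0.975), names = FALSE))
  }
  summ <- t(apply(draws[, c("delta_cost", "delta_qaly", "nmb"),
                        drop = FALSE], 2, qs))
  summary_df <- data.frame(quantity = rownames(summ), median = summ[, 1],
                           ci_lower = summ[, 2], ci_upper = summ[, 3],
                           row.names = NULL, stringsAsFactors = FALSE)

  breakeven <- spec$drug_cost_annual + stats::median(draws[, "nmb"])
  verified <- NA_real_
  if (.verify_breakeven) {
    spec_be <- spec
    spec_be$drug_cost_annual <- breakeven
    re <- run_intervention_sim(spec_be, effects, counts,
                               .verify_breakeven = FALSE)
    verified <- re$summary$median[re$summary$quantity == "nmb"]
  }

  structure(list(
    summary = summary_df,
    breakeven_price = breakeven,
    breakeven_verified_nmb = verified,
    scenario = counts$label,
    source = effects$source,
    spec = spec,
    effects = effects,
    counts = counts,
    draws = if (keep_draws) draws else NULL
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness simulation: scenario '%s' (%s), %d draws\n",
              x$scenario, x$source, x$spec$n_draws))
  s <- x$summary
  fmt <- c(delta_cost = "GBP/person/year", delta_qaly = "pp QALY/person/year",
           nmb = "GBP/person/year")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %9.2f  [%.2f, %.2f]  %s\n", s$quantity[i],
                s$median[i], s$ci_lower[i], s$ci_upper[i],
                fmt[[s$quantity[i]]]))
  }
  cat(sprintf("  break-even annual drug price: GBP %.2f", x$breakeven_price))
  if (is.finite(x$breakeven_verified_nmb)) {
    cat(sprintf(" (median NMB at that price: %.2f)", x$breakeven_verified_nmb))
  }
  cat("\n")
  invisible(x)
}

#' Tidy CEA results into a scenario x quantity table
#'
#' @param ... `cea_result` objects.
#' @return data frame: scenario, source, quantity, median, ci_lower,
#'   ci_upper, breakeven_price.
#' @export
cea_results_table <- function(...) {
  res <- list(...)
  do.call(rbind, lapply(res, function(r) {
    cbind(scenario = r$scenario, source = r$source, r$summary,
          breakeven_price = r$breakeven_price, stringsAsFactors = FALSE)
  }))
}
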