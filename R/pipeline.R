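#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or JSON) with sections `generator` (parameters
#' for [cohort_params()]), `analysis` (PRS scheme, outcomes, number of
#' imputations, optional strata), `intervention` (odds ratio and CI, drug
#' cost, threshold, draw count, scenario counts, and either fixed effect
#' inputs or `effects: from_mr`), and a global `seed` from which every stage
#' derives a named substream. Schema violations are reported with the path
#' of the offending field.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config a configuration list (already parsed).
#' @export
validate_pipeline_config <- function(config) {
  bad <- function(field, msg) {
    stop(sprintf("config schema violation at `%s`: %s", field, msg),
         call. = FALSE)
  }
  need <- function(field) {
    node <- config
    for (part in strsplit(field, ".", fixed = TRUE)[[1]]) {
      node <- node[[part]]
      if (is.null(node)) bad(field, "required field is missing")
    }
    node
  }
  need("seed")
  n <- need("generator.n_individuals")
  if (!is.numeric(n) || n < 1) bad("generator.n_individuals",
                                   "must be a positive count")
  need("intervention.or")
  ci <- need("intervention.or_ci")
  if (length(ci) != 2) bad("intervention.or_ci", "must be a pair")
  need("intervention.drug_cost_annual")
  need("intervention.counts.n_cases")
  need("intervention.counts.n_total")
  eff <- config$intervention$effects
  if (!is.null(eff) && !identical(eff, "from_mr")) {
    for (f in c("cost_effect", "cost_ci", "qaly_effect", "qaly_ci")) {
      if (is.null(eff[[f]])) bad(paste0("intervention.effects.", f),
                                 "required field is missing")
    }
  }
  sch <- config$analysis$scheme %||% "beta"
  if (!sch %in% c("beta", "precision")) bad("analysis.scheme",
                                            "must be 'beta' or 'precision'")
  structure(config, class = c("pipeline_config", "list"))
}

config_generator_params <- function(config, seed) {
  g <- config$generator
  args <- g[intersect(names(g), names(formals(cohort_params)))]
  args$seed <- seed
  do.call(cohort_params, args)
}

pipeline_comments <- function(config, seed) {
  c(paste0("mrcea ", as.character(utils::packageVersion("mrcea"))),
    paste0("seed: ", seed),
    paste0("config_hash: ",
           fnv1a_hash(paste(utils::capture.output(utils::str(config)),
                            collapse = "\n"))))
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` -> `prs` -> `mr` -> `sensitivity` ->
#' `cea`, writing each stage's outputs to `out_dir` as delimiter-explicit
#' UTF-8 text files whose headers carry provenance comments (package
#' version, seed, config hash). Stages can be run individually provided the
#' inputs they need are already present in `out_dir`. Any stage error
#' removes the files written by this invocation before rethrowing, so no
#' partial outputs are left behind.
#'
#' Outputs: `cohort.csv`, `dosages.tsv`, `weights.tsv`, `truth.json`
#' (simulate); `prs.csv` (prs); `mr_results.csv` (mr: one row per outcome x
#' method, 2SLS and OLS with Hausman p-values, Rubin's-rules pooled over
#' imputations when costs are missing); `sensitivity_per_snp.csv` and
#' `sensitivity_pooled.csv` (sensitivity); `cea_results.csv` (cea).
#'
#' @param config a `pipeline_config` (from [read_pipeline_config()]), or a
#'   path to one.
#' @param out_dir output directory, created if needed.
#' @param stages character vector of stages to run, in order; default all.
#' @param seed optional override of the config's global seed.
#' @param quiet suppress progress messages.
#' @return invisibly, a named character vector of output paths.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "prs", "mr", "sensitivity",
                                    "cea"),
                         seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comments <- pipeline_comments(config, seed)
  say <- function(...) if (!quiet) message(...)

  written <- character()
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }

  paths <- c(
    cohort = file.path(out_dir, "cohort.csv"),
    dosages = file.path(out_dir, "dosages.tsv"),
    weights = file.path(out_dir, "weights.tsv"),
    truth = file.path(out_dir, "truth.json"),
    prs = file.path(out_dir, "prs.csv"),
    mr = file.path(out_dir, "mr_results.csv"),
    snp = file.path(out_dir, "sensitivity_per_snp.csv"),
    pooled = file.path(out_dir, "sensitivity_pooled.csv"),
    cea = file.path(out_dir, "cea_results.csv")
  )

  tryCatch({
    if ("simulate" %in% stages) {
      say("stage simulate")
      params <- config_generator_params(config, stage_seed(seed, "simulate"))
      sim <- generate_cohort(params)
      write_cohort(sim$cohort, paths[["cohort"]], comments = comments)
      write_dosages(sim$dosages, paths[["dosages"]], ids = sim$cohort$id,
                    comments = comments)
      write_weight_table(sim$weights, paths[["weights"]], comments = comments)
      write_truth(sim$truth, paths[["truth"]])
      written <- c(written, paths[c("cohort", "dosages", "weights", "truth")])
    }

    need_file <- function(key, field) {
      if (!file.exists(paths[[key]])) {
        stop(sprintf("config schema violation at `%s`: input file %s not found",
                     field, paths[[key]]), call. = FALSE)
      }
    }

    scheme <- config$analysis$scheme %||% "beta"
    outcomes <- config$analysis$outcomes %||% c("annual_cost", "annual_qaly")

    if (any(c("prs", "mr", "sensitivity") %in% stages)) {
      need_file("cohort", "paths.cohort")
      need_file("dosages", "paths.dosages")
      need_file("weights", "paths.weights")
      cohort <- read_cohort(paths[["cohort"]])
      dosages <- read_dosages(paths[["dosages"]])
      weights <- read_weight_table(paths[["weights"]])
      prs <- build_prs(dosages, weights, scheme = scheme)
    }

    if ("prs" %in% stages) {
      say("stage prs")
      r2 <- pseudo_r2(cohort$cancer, prs)
      write_prs(prs, cohort$id, paths[["prs"]],
                comments = c(comments, sprintf("pseudo_r2: %.6g", r2)))
      written <- c(written, paths[["prs"]])
    }

    mr_ests <- NULL
    if ("mr" %in% stages) {
      say("stage mr")
      m <- config$analysis$m_imputations %||% 5
      mr_seed <- stage_seed(seed, "mr")
      covs <- mr_covariates(cohort)
      rows <- list()
      mr_ests <- list()
      for (o in outcomes) {
        fit_iv <- function(ch) {
          fit_2sls(outcome_values(ch, o), ch$cancer, prs, mr_covariates(ch),
                   outcome_label = o, exposure_label = "cancer")
        }
        fit_mv <- function(ch) {
          fit_ols(outcome_values(ch, o), ch$cancer, mr_covariates(ch),
                  outcome_label = o, exposure_label = "cancer")
        }
        iv <- if (o == "annual_cost" && any(cohort$cost_missing)) {
          impute_and_pool(cohort, m, fit_iv, seed = mr_seed)
        } else fit_iv(cohort)
        mv <- if (o == "annual_cost" && any(cohort$cost_missing)) {
          impute_and_pool(cohort, m, fit_mv, seed = mr_seed + 1L)
        } else fit_mv(cohort)
        h <- hausman_test(iv, mv)
        tab <- mr_results_table(iv, mv)
        tab$hausman_p <- h$p_value
        rows[[o]] <- tab
        mr_ests[[o]] <- iv
      }
      write_table_commented(do.call(rbind, rows), paths[["mr"]], sep = ",",
                            comments = comments)
      written <- c(written, paths[["mr"]])
    }

    if ("sensitivity" %in% stages) {
      say("stage sensitivity")
      covs <- mr_covariates(cohort)
      use <- !is.na(cohort$annual_cost)
      per <- per_snp_estimates(cohort$cancer[use], cohort$annual_cost[use],
                               dosages[use, , drop = FALSE],
                               covs[use, , drop = FALSE])
      pooled <- ivw_pool(per)
      write_table_commented(as.data.frame(per), paths[["snp"]], sep = ",",
                            comments = comments)
      write_table_commented(
        data.frame(beta_pooled = pooled$beta_pooled,
                   se_pooled = pooled$se_pooled,
                   q_statistic = pooled$q_statistic, q_df = pooled$q_df,
                   q_pvalue = pooled$q_pvalue, n_snps = pooled$n_snps),
        paths[["pooled"]], sep = ",", comments = comments)
      written <- c(written, paths[c("snp", "pooled")])
    }

    if ("cea" %in% stages) {
      say("stage cea")
      iv <- config$intervention
      eff_cfg <- iv$effects
      effects <- if (is.null(eff_cfg) || identical(eff_cfg, "from_mr")) {
        if (is.null(mr_ests)) {
          need_file("mr", "intervention.effects")
          mr_tab <- utils::read.csv(paths[["mr"]], comment.char = "#")
          pick <- function(o) mr_tab[mr_tab$outcome == o &
                                       mr_tab$method == "2sls", ][1, ]
          co <- pick("annual_cost")
          qa <- pick("annual_qaly")
          effect_input(co$beta, c(co$ci_lower, co$ci_upper),
                       qa$beta, c(qa$ci_lower, qa$ci_upper),
                       source = "mendelian_randomization")
        } else {
          co <- mr_ests[["annual_cost"]]
          qa <- mr_ests[["annual_qaly"]]
          effect_input(co$beta, co$ci95, qa$beta, qa$ci95,
                       source = "mendelian_randomization")
        }
      } else {
        effect_input(eff_cfg$cost_effect, eff_cfg$cost_ci,
                     eff_cfg$qaly_effect, eff_cfg$qaly_ci,
                     source = eff_cfg$source %||% "mendelian_randomization")
      }
      spec <- intervention_spec(
        or_point = iv$or, or_ci95 = iv$or_ci,
        drug_cost_annual = iv$drug_cost_annual,
        wtp_threshold = iv$wtp_threshold %||% 20000,
        n_draws = iv$n_draws %||% 10000,
        seed = stage_seed(seed, "cea"),
        or_scale = iv$or_scale %||% "log"
      )
      counts <- stratum_counts(iv$counts$n_cases, iv$counts$n_total,
                               label = iv$counts$label %||% "all")
      res <- run_intervention_sim(spec, effects, counts)
      write_table_commented(cea_results_table(res), paths[["cea"]], sep = ",",
                            comments = comments)
      written <- c(written, paths[["cea"]])
    }
  }, error = on_fail_cleanup)

  invisible(paths)
}
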