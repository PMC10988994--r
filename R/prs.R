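#' Build a polygenic risk score from a weight table and dosages
#'
#' Computes the per-individual weighted allele count used as the single
#' instrument in the just-identified two-stage least squares models. Under
#' the default `"beta"` scheme the score is `sum_j beta_j * dosage_ij`; the
#' `"precision"` scheme weights each log-odds ratio by its precision,
#' `sum_j (beta_j / se_j^2) * dosage_ij`. Downstream 2SLS point estimates are
#' invariant to the instrument's scale, so the scheme mainly affects the
#' score's units.
#'
#' Variant sets are harmonised by id. When allele information is available
#' for the dosage columns (either via the matrix's `alleles` attribute, as
#' written by [generate_cohort()], or via `dosage_alleles`), a variant whose
#' weight-table effect allele is the dosage's other allele is flipped
#' (`d -> 2 - d`). Harmonisation assumes both sources refer to the same
#' strand; strand-ambiguous (A/T, C/G) variants are accepted unchanged but
#' flagged with a message.
#'
#' @param dosages individuals x variants matrix of dosages in \[0, 2\].
#' @param weights GWAS weight table with columns variant, effect_allele,
#'   other_allele, beta, se.
#' @param scheme `"beta"` (default) or `"precision"`.
#' @param dosage_alleles optional data frame (variant, effect_allele,
#'   other_allele) describing the allele counted by each dosage column;
#'   overrides the matrix attribute.
#' @return numeric vector of scores (one per individual) with attributes
#'   `scheme` and `variants`. A zero-variance score triggers a warning, which
#'   propagates to the first-stage F diagnostic downstream.
#' @examples
#' d <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "rs1"))
#' w <- data.frame(variant = "rs1", effect_allele = "A", other_allele = "G",
#'                 beta = log(2), se = 0.1)
#' build_prs(d, w)
#' @export
build_prs <- function(dosages, weights, scheme = c("beta", "precision"),
                      dosage_alleles = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(dosages), is.data.frame(weights))
  if (any(weights$se <= 0)) stop("weight table standard errors must be > 0")
  if (anyDuplicated(weights$variant)) {
    stop("weight table variant ids must be unique")
  }
  missing_ids <- setdiff(weights$variant, colnames(dosages))
  if (length(missing_ids)) {
    stop("variant(s) in weight table absent from dosages: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  D <- dosages[, weights$variant, drop = FALSE]

  alleles <- dosage_alleles %||% attr(dosages, "alleles")
  if (!is.null(alleles)) {
    al <- alleles[match(weights$variant, alleles$variant), , drop = FALSE]
    same <- weights$effect_allele == al$effect_allele &
      weights$other_allele == al$other_allele
    flipped <- weights$effect_allele == al$other_allele &
      weights$other_allele == al$effect_allele
    bad <- !(same | flipped) & !is.na(al$effect_allele)
    if (any(bad)) {
      stop("allele mismatch beyond a simple flip for variant(s): ",
           paste(weights$variant[bad], collapse = ", "), call. = FALSE)
    }
    if (any(flipped, na.rm = TRUE)) {
      idx <- which(flipped)
      D[, idx] <- 2 - D[, idx]
    }
    ambiguous <- toupper(paste0(weights$effect_allele, weights$other_allele)) %in%
      c("AT", "TA", "CG", "GC")
    if (any(ambiguous)) {
      message("strand-ambiguous variant(s) accepted unchanged: ",
              paste(weights$variant[ambiguous], collapse = ", "))
    }
  }

  w <- switch(scheme,
              beta = weights$beta,
              precision = weights$beta / weights$se^2)
  score <- as.numeric(D %*% w)
  if (stats::var(score) == 0) {
    warning("polygenic score has zero variance; downstream first-stage ",
            "F-statistics will be undefined", call. = FALSE)
  }
  structure(score, scheme = scheme, variants = weights$variant)
}

#' McFadden pseudo-R-squared of a cancer on its polygenic score
#'
#' Fits a logistic regression of the binary cancer status on an intercept and
#' the polygenic score (IRLS, convergence tolerance 1e-8, at most 100
#' iterations) and reports McFadden's pseudo-R-squared,
#' `1 - logLik(full) / logLik(null)`. This is the instrument-relevance summary
#' reported alongside each score.
#'
#' @param cancer binary 0/1 vector.
#' @param prs numeric polygenic score vector of the same length.
#' @return pseudo-R-squared in \[0, 1).
#' @export
pseudo_r2 <- function(cancer, prs) {
  cancer <- as.numeric(cancer)
  stopifnot(length(cancer) == length(prs))
  if (!all(cancer %in% c(0, 1))) stop("`cancer` must be binary 0/1")
  if (length(unique(cancer)) < 2) {
    stop("both cancer classes must be present")
  }
  fit <- withCallingHandlers(
    stats::glm(cancer ~ prs, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("possible complete separation of cancer status by the score",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) {
    stop("logistic regression did not converge within 100 iterations")
  }
  ll_full <- as.numeric(stats::logLik(fit))
  ll_null <- as.numeric(stats::logLik(
    stats::glm(cancer ~ 1, family = stats::binomial())
  ))
  1 - ll_full / ll_null
}

#' Write a polygenic score as a two-column CSV
#'
#' @param prs numeric score vector from [build_prs()].
#' @param ids individual ids.
#' @param path file path.
#' @param comments optional character vector written as leading `#` lines.
#' @return `path`, invisibly. `read_prs` returns a data frame (id, score)
#'   with the scheme (if recorded on write) available as a comment only.
#' @export
write_prs <- function(prs, ids, path, comments = NULL) {
  df <- data.frame(id = ids, score = as.numeric(prs),
                   stringsAsFactors = FALSE)
  write_table_commented(df, path, sep = ",",
                        comments = c(comments,
                                     paste0("scheme: ",
                                            attr(prs, "scheme") %||% "beta")))
  invisible(path)
}

#' @rdname write_prs
#' @export
read_prs <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
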