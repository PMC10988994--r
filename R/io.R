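# Readers and writers for the package's plain-text exchange formats.
# Genetic matrices are TSV, analysis tables CSV, ground truth JSON.
# All writers are locale-independent (C-style numbers, "." decimal).
# Optional `comments` are written as leading "#" lines and skipped on read.

write_table_commented <- function(df, path, sep, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
}

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort data frame as produced by [generate_cohort()].
#' @param path file path.
#' @param comments optional character vector written as leading `#` lines.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort data frame with `sex` restored as a factor.
#' @export
write_cohort <- function(cohort, path, comments = NULL) {
  write_table_commented(cohort, path, sep = ",", comments = comments)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$cost_missing <- as.logical(df$cost_missing)
  df
}

#' Write / read a dosage matrix as TSV
#'
#' One row per individual, one column per variant, values in \[0, 2\]; the
#' first column holds individual ids.
#'
#' @param dosages numeric matrix (individuals x variants) with variant ids as
#'   column names.
#' @param path file path.
#' @param ids individual ids for the first column; defaults to the matrix
#'   rownames or a running index.
#' @param comments optional character vector written as leading `#` lines.
#' @return `write_dosages` returns `path` invisibly; `read_dosages` returns
#'   the matrix with ids as rownames.
#' @export
write_dosages <- function(dosages, path, ids = NULL, comments = NULL) {
  ids <- ids %||% rownames(dosages) %||% sprintf("id%06d", seq_len(nrow(dosages)))
  df <- data.frame(id = ids, dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_commented(df, path, sep = "\t", comments = comments)
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a GWAS weight table as TSV
#'
#' Columns: variant, effect_allele, other_allele, beta (log-odds ratio),
#' se (standard error of beta).
#'
#' @param weights weight-table data frame.
#' @param path file path.
#' @param comments optional character vector written as leading `#` lines.
#' @return `write_weight_table` returns `path` invisibly; `read_weight_table`
#'   returns the data frame.
#' @export
write_weight_table <- function(weights, path, comments = NULL) {
  stopifnot(all(c("variant", "effect_allele", "other_allele", "beta", "se")
                %in% names(weights)))
  write_table_commented(weights, path, sep = "\t", comments = comments)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(df$se <= 0)) stop("weight table has non-positive standard errors")
  if (anyDuplicated(df$variant)) stop("weight table has duplicate variant ids")
  df
}

#' Write / read a ground-truth record as JSON
#'
#' @param truth truth list from an `mr_sim` object.
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an mr_sim bundle to a directory
#'
#' Writes cohort.csv, dosages.tsv, weights.tsv and truth.json.
#'
#' @param sim an `mr_sim` object.
#' @param dir output directory (created if needed).
#' @param comments optional provenance comment lines for the tabular files.
#' @return invisibly, a named character vector of the written paths.
#' @export
write_sim <- function(sim, dir, comments = NULL) {
  stopifnot(inherits(sim, "mr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    dosages = file.path(dir, "dosages.tsv"),
    weights = file.path(dir, "weights.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_cohort(sim$cohort, paths[["cohort"]], comments = comments)
  write_dosages(sim$dosages, paths[["dosages"]], ids = sim$cohort$id,
                comments = comments)
  write_weight_table(sim$weights, paths[["weights"]], comments = comments)
  write_truth(sim$truth, paths[["truth"]])
  invisible(paths)
}
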