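#' Construct a cohort matrix of binary complication indicators
#'
#' The universal input of the pipeline: an N x V matrix with one row per
#' patient and one 0/1 column per catalog variable. All entries must be
#' exactly 0 or 1 -- missing values are rejected, not imputed, because the
#' analysis cohort is defined as patients with complete complication
#' information.
#'
#' @param values Numeric or integer matrix (or data frame) of 0/1 indicators
#'   with column names matching the catalog.
#' @param catalog A [variable_catalog()]; if `NULL`, one is built from the
#'   column names with `outcome` as the flagged variable.
#' @param outcome Outcome variable name used when `catalog` is `NULL`.
#'
#' @return An object of class `cohort_matrix`: list with `values` (integer
#'   matrix) and `catalog`.
#' @seealso [read_cohort()], [filter_any_complication()]
#' @export
cohort_matrix <- function(values, catalog = NULL, outcome = "death") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) {
    cn_validation_error("values must be a matrix or data frame")
  }
  if (nrow(values) < 1L) {
    cn_validation_error("a cohort needs at least one patient (N >= 1)")
  }
  if (is.null(colnames(values))) {
    if (is.null(catalog)) {
      cn_validation_error("values must have column names or a catalog")
    }
    colnames(values) <- catalog$names
  }
  if (is.null(catalog)) {
    catalog <- variable_catalog(colnames(values), outcome = outcome)
  }
  if (ncol(values) != length(catalog$names) ||
      !identical(colnames(values), catalog$names)) {
    cn_validation_error("column names must match the catalog exactly")
  }
  storage.mode(values) <- "integer"
  bad <- which(is.na(values) | (values != 0L & values != 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cn_validation_error(sprintf(
      "non-binary value at row %d, column '%s'",
      bad[1L, 1L], catalog$names[bad[1L, 2L]]
    ))
  }
  structure(list(values = values, catalog = catalog),
            class = "cohort_matrix")
}

#' Number of patients in a cohort
#' @param cohort A `cohort_matrix`.
#' @return Integer row count.
#' @export
n_patients <- function(cohort) nrow(cohort$values)

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("Cohort matrix: %d patients x %d variables (outcome: %s)\n",
              nrow(x$values), ncol(x$values), x$catalog$outcome))
  prev <- colMeans(x$values)
  cat(sprintf("  prevalence range: %.3f - %.3f\n", min(prev), max(prev)))
  invisible(x)
}

#' Read a patient-level cohort from delimited text
#'
#' Expects a header row naming the variables and a body of binary cells.
#' Accepted encodings per cell: `0`, `1`, `true`, `false` (case-insensitive).
#' Anything else -- including empty cells and `NA` -- is a validation error
#' that names the offending row and column.
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field separator, default `","`.
#' @param outcome Name of the outcome column (default `"death"`).
#' @return A [cohort_matrix()]; row order of the file is preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("death,stroke", "0,0", "1,1", "0,1"), f)
#' read_cohort(f)
#' @export
read_cohort <- function(path, delimiter = ",", outcome = "death") {
  if (!file.exists(path)) {
    cn_io_error(sprintf("file not found: %s", path))
  }
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 2L) {
    cn_format_error("cohort files need at least 2 columns")
  }
  header <- as.character(unlist(raw[1L, ], use.names = FALSE))
  if (anyNA(header) || any(!nzchar(header))) {
    cn_format_error("missing column name in header row")
  }
  if (anyDuplicated(header)) {
    cn_format_error(sprintf(
      "duplicate column name(s) in header: %s",
      paste(unique(header[duplicated(header)]), collapse = ", ")
    ))
  }
  if (nrow(raw) < 2L) {
    cn_validation_error("cohort file has a header but no patients")
  }
  body <- as.matrix(raw[-1L, , drop = FALSE])
  parsed <- matrix(NA_integer_, nrow(body), ncol(body))
  lowered <- tolower(trimws(body))
  parsed[lowered == "0" | lowered == "false"] <- 0L
  parsed[lowered == "1" | lowered == "true"] <- 1L
  bad <- which(is.na(parsed), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cn_validation_error(sprintf(
      "cell '%s' at data row %d, column '%s' is not binary (expected 0/1/true/false)",
      body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], header[bad[1L, 2L]]
    ))
  }
  colnames(parsed) <- header
  cohort_matrix(parsed, outcome = outcome)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: header row plus one 0/1 row per patient.
#'
#' @param cohort A `cohort_matrix`.
#' @param path Destination path.
#' @param delimiter Field separator, default `","`.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, delimiter = ",") {
  stopifnot(inherits(cohort, "cohort_matrix"))
  ok <- tryCatch({
    utils::write.table(cohort$values, file = path, sep = delimiter,
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    cn_io_error(sprintf("cannot write cohort to '%s': %s",
                        path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Restrict a cohort to patients with at least one complication
#'
#' Keeps rows where at least one non-outcome column equals 1. The outcome
#' column does not count: a patient who died without any recorded
#' complication is dropped. This reproduces the analysis-cohort definition
#' used for network learning (patients with >= 1 complication).
#'
#' @param cohort A `cohort_matrix` whose catalog flags the outcome.
#' @return A `cohort_matrix` with the same catalog; idempotent.
#' @export
filter_any_complication <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  comp <- complication_names(cohort$catalog)
  keep <- rowSums(cohort$values[, comp, drop = FALSE]) > 0L
  if (!any(keep)) {
    cn_validation_error("no patients with complications after filtering")
  }
  cohort$values <- cohort$values[keep, , drop = FALSE]
  cohort
}
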