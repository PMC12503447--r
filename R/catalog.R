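#' Variable catalog for a complication cohort
#'
#' A catalog is the ordered list of binary variables in a cohort together
#' with a flag marking exactly one of them as the terminal outcome (death).
#' Every other structure in the package -- cohorts, DAGs, conditional
#' probability tables -- is indexed by catalog names.
#'
#' @param names Character vector of unique, non-empty variable names.
#' @param outcome Name of the single outcome variable; must be in `names`.
#'
#' @return An object of class `variable_catalog`: a list with elements
#'   `names` and `outcome`.
#' @examples
#' variable_catalog(c("stroke", "mods", "death"), outcome = "death")
#' @export
variable_catalog <- function(names, outcome = "death") {
  if (!is.character(names) || length(names) < 2L) {
    cn_validation_error("a catalog needs at least two variable names")
  }
  if (anyNA(names) || any(!nzchar(names))) {
    cn_validation_error("catalog names must be non-empty strings")
  }
  if (anyDuplicated(names)) {
    dup <- unique(names[duplicated(names)])
    cn_validation_error(sprintf(
      "duplicate variable name(s): %s", paste(dup, collapse = ", ")
    ))
  }
  if (!is.character(outcome) || length(outcome) != 1L || !outcome %in% names) {
    cn_validation_error("outcome must name exactly one catalog variable")
  }
  structure(list(names = names, outcome = outcome),
            class = "variable_catalog")
}

#' Default 13-variable perioperative complication catalog
#'
#' The canonical set used throughout the package: 12 perioperative
#' complications of valve surgery plus 30-day death. Names are lowercase
#' snake_case and match the column headers expected in cohort files.
#'
#' @return A [variable_catalog()] with 13 entries, outcome `"death"`.
#' @export
default_catalog <- function() {
  variable_catalog(
    c("increased_chest_tube_drainage",
      "prolonged_icu_stays",
      "prolonged_mechanical_ventilation",
      "postoperative_af",
      "postoperative_mi",
      "sternal_wound_infections",
      "pericardial_tamponade",
      "reoperation",
      "secondary_tracheal_intubation",
      "stroke",
      "postoperative_rf",
      "mods",
      "death"),
    outcome = "death"
  )
}

#' @export
print.variable_catalog <- function(x, ...) {
  cat(sprintf("Variable catalog: %d variables (outcome: %s)\n",
              length(x$names), x$outcome))
  cat(paste0("  ", x$names, ifelse(x$names == x$outcome, " *", "")),
      sep = "\n")
  invisible(x)
}

# Non-outcome variable names, in catalog order.
complication_names <- function(catalog) {
  setdiff(catalog$names, catalog$outcome)
}
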