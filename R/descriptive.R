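#' Per-complication frequency and mortality summary
#'
#' For each non-outcome variable: how many patients carry the complication,
#' what percentage of the cohort that is, how many carriers died, and the
#' death percentage among carriers. Percentages are rounded half-up to one
#' decimal (the convention of clinical frequency tables); the raw ratios
#' are kept in `pct_with_raw` / `pct_death_raw`.
#'
#' The percentage denominator is the number of patients with at least one
#' complication by default (the analysis-cohort convention); use
#' `denominator = "all"` to report over every row.
#'
#' @param cohort A `cohort_matrix` with a flagged outcome.
#' @param denominator `"with_complication"` (default) or `"all"`.
#' @return Object of class `marginal_summary`: a data frame with columns
#'   `variable`, `count_with`, `pct_with`, `deaths_after`, `pct_death`
#'   (`NA` when a complication has zero carriers), plus raw-precision
#'   columns. Attribute `denominator_n` records the denominator used.
#' @export
marginal_summary <- function(cohort,
                             denominator = c("with_complication", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(cohort, "cohort_matrix"))
  comp <- complication_names(cohort$catalog)
  values <- cohort$values
  died <- values[, cohort$catalog$outcome] == 1L
  denom <- if (denominator == "all") {
    nrow(values)
  } else {
    sum(rowSums(values[, comp, drop = FALSE]) > 0L)
  }
  count_with <- colSums(values[, comp, drop = FALSE])
  deaths_after <- colSums(values[died, comp, drop = FALSE])
  pct_with_raw <- 100 * count_with / denom
  pct_death_raw <- ifelse(count_with > 0, 100 * deaths_after / count_with,
                          NA_real_)
  out <- data.frame(
    variable = comp,
    count_with = as.integer(count_with),
    pct_with = round_half_up(pct_with_raw, 1),
    deaths_after = as.integer(deaths_after),
    pct_death = round_half_up(pct_death_raw, 1),
    pct_with_raw = pct_with_raw,
    pct_death_raw = pct_death_raw,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(out, class = c("marginal_summary", "data.frame"),
            denominator = denominator, denominator_n = denom)
}

#' Co-occurrence summary of complications
#'
#' Three views of how complications cluster within patients, all over the
#' non-outcome columns: the multiplicity histogram (how many patients have
#' exactly k complications), the per-complication co-occurrence rate (the
#' fraction of a complication's carriers who have at least one *other*
#' complication), and the counts of each observed complication-set pattern.
#'
#' @param cohort A `cohort_matrix`.
#' @return Object of class `cooccurrence_summary`: list with
#'   `multiplicity_counts` (named integer vector over k = 0..V-1, zeros
#'   kept), `cooccur_rate` (named numeric, `NA` for complications with no
#'   carriers), and `pattern_counts` (data frame `pattern`, `count`;
#'   patterns are `+`-joined sorted complication names, `""` for none).
#' @export
cooccurrence_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  comp <- complication_names(cohort$catalog)
  values <- cohort$values[, comp, drop = FALSE]
  k <- rowSums(values)
  mult <- tabulate(k + 1L, nbins = length(comp) + 1L)
  names(mult) <- 0:length(comp)
  carriers <- colSums(values)
  with_other <- colSums(values * (k > 1L))
  rate <- ifelse(carriers > 0, with_other / carriers, NA_real_)
  names(rate) <- comp
  pattern <- apply(values, 1L, function(row) {
    paste(comp[row == 1L], collapse = "+")
  })
  tab <- table(pattern)
  pattern_counts <- data.frame(pattern = names(tab),
                               count = as.integer(tab),
                               stringsAsFactors = FALSE)
  pattern_counts <- pattern_counts[order(-pattern_counts$count,
                                         pattern_counts$pattern), ,
                                   drop = FALSE]
  rownames(pattern_counts) <- NULL
  structure(list(multiplicity_counts = mult,
                 cooccur_rate = rate,
                 pattern_counts = pattern_counts),
            class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  n_multi <- sum(x$multiplicity_counts[as.integer(names(x$multiplicity_counts)) >= 2])
  n_any <- sum(x$multiplicity_counts[as.integer(names(x$multiplicity_counts)) >= 1])
  cat("Co-occurrence summary\n")
  cat(sprintf("  patients with >= 2 complications: %d (%.1f%% of those with any)\n",
              n_multi, 100 * n_multi / max(n_any, 1L)))
  invisible(x)
}

#' Phi coefficient matrix
#'
#' Pairwise phi coefficients between all catalog variables, computed from
#' each pair's 2x2 contingency table as
#' `(n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`. For binary variables this
#' equals the Pearson correlation of the 0/1 columns. Pairs involving a
#' zero-variance column are undefined and reported as `NA`; the count of
#' such pairs is attached as the `n_undefined` attribute rather than
#' letting NaN propagate silently.
#'
#' @param cohort A `cohort_matrix`.
#' @return Object of class `phi_matrix`: a symmetric V x V numeric matrix
#'   with unit diagonal, attributes `n_used` (rows) and `n_undefined`.
#' @export
phi_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  x <- cohort$values
  n <- nrow(x)
  ones <- colSums(x)
  n11 <- crossprod(x)                      # joint 1-1 counts
  n1_ <- matrix(ones, nrow = ncol(x), ncol = ncol(x))        # row var count
  n_1 <- t(n1_)                                              # col var count
  n10 <- n1_ - n11
  n01 <- n_1 - n11
  n00 <- n - n11 - n10 - n01
  denom <- sqrt(n1_) * sqrt(n - n1_) * sqrt(n_1) * sqrt(n - n_1)
  phi <- (n11 * n00 - n10 * n01) / denom
  degenerate <- ones == 0L | ones == n
  phi[degenerate, ] <- NA_real_
  phi[, degenerate] <- NA_real_
  diag(phi) <- ifelse(degenerate, NA_real_, 1)
  dimnames(phi) <- list(cohort$catalog$names, cohort$catalog$names)
  n_undef <- sum(is.na(phi[upper.tri(phi, diag = TRUE)]))
  structure(phi, class = c("phi_matrix", "matrix", "array"),
            n_used = n, n_undefined = n_undef)
}

#' Collinearity diagnostics of the indicator matrix
#'
#' Pearson correlation matrix over all catalog columns, its eigenvalues,
#' and a condition number summarising their spread. The default condition
#' number is `sqrt(lambda_max / lambda_min)` -- the convention under which
#' a value above 30 indicates severe multicollinearity; `method = "ratio"`
#' reports the plain eigenvalue ratio instead. A singular correlation
#' matrix (zero smallest eigenvalue, e.g. a duplicated column) yields an
#' infinite condition number with the severity flag set.
#'
#' @param cohort A `cohort_matrix` with at least two non-degenerate
#'   columns.
#' @param method `"sqrt_ratio"` (default) or `"ratio"`.
#' @return Object of class `collinearity_report`: list with
#'   `correlation_matrix`, `eigenvalues` (descending), `condition_number`,
#'   `flag_severe`, `method`, `threshold` (30).
#' @export
collinearity_report <- function(cohort, method = c("sqrt_ratio", "ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort_matrix"))
  x <- cohort$values
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  if (sum(keep) < 2L) {
    cn_validation_error("need at least two columns with nonzero variance")
  }
  cm <- stats::cor(x[, keep, drop = FALSE])
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  ev[ev < 0 & ev > -1e-12] <- 0  # clip eigensolver noise; PSD by theory
  lmin <- ev[length(ev)]
  tol <- 1e-12 * ev[1L]
  cn <- if (lmin <= tol) {
    Inf
  } else if (method == "sqrt_ratio") {
    sqrt(ev[1L] / lmin)
  } else {
    ev[1L] / lmin
  }
  structure(list(correlation_matrix = cm,
                 eigenvalues = ev,
                 condition_number = cn,
                 flag_severe = cn > 30,
                 method = method,
                 threshold = 30,
                 dropped_degenerate = cohort$catalog$names[!keep]),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("Collinearity report (%s): condition number %.6f%s\n",
              x$method, x$condition_number,
              if (x$flag_severe) "  ** severe (>30)" else ""))
  invisible(x)
}

#' Reference per-complication frequency and mortality counts
#'
#' The printed frequency/mortality table for a registry cohort of 18,585
#' valve-surgery patients with at least one complication: per complication,
#' the number of carriers and the number of carriers who died within 30
#' days. Used to validate the summary arithmetic and to build patient-level
#' fixtures with exactly these column counts.
#'
#' @return Data frame with columns `variable`, `count_with`,
#'   `deaths_after`; attribute `n_cohort` = 18585.
#' @export
reference_counts <- function() {
  df <- data.frame(
    variable = complication_names(default_catalog()),
    count_with = c(9312L, 9321L, 8489L, 484L, 181L, 94L, 163L, 1068L,
                   537L, 92L, 453L, 299L),
    deaths_after = c(448L, 460L, 579L, 39L, 15L, 19L, 33L, 174L,
                     202L, 33L, 223L, 274L),
    stringsAsFactors = FALSE
  )
  attr(df, "n_cohort") <- 18585L
  df
}

#' Build a patient-level cohort matching given marginal counts
#'
#' Constructs an N x 13 binary matrix in which each complication has
#' exactly `count_with` carriers, exactly `deaths_after` of whom are also
#' death-positive, and every patient has at least one complication. Because
#' [marginal_summary()] depends only on column counts and their overlap
#' with the death column, any such matrix reproduces the reference
#' percentages exactly; the row-level co-occurrence pattern is a synthetic
#' construction (round-robin assignment) and carries no information.
#'
#' @param reference Data frame with `variable`, `count_with`,
#'   `deaths_after` (default [reference_counts()]).
#' @param n Cohort size (default the reference's `n_cohort` attribute).
#' @param n_deaths Total number of death-positive rows; defaults to the
#'   largest `deaths_after` (every dying carrier set fits inside the death
#'   block).
#' @return A [cohort_matrix()].
#' @export
cohort_from_marginals <- function(reference = reference_counts(),
                                  n = NULL, n_deaths = NULL) {
  n <- as.integer(n %||% attr(reference, "n_cohort"))
  n_deaths <- as.integer(n_deaths %||% max(reference$deaths_after))
  if (any(reference$deaths_after > reference$count_with)) {
    cn_validation_error("deaths_after cannot exceed count_with")
  }
  if (n_deaths < max(reference$deaths_after)) {
    cn_validation_error("n_deaths must cover the largest deaths_after")
  }
  n_alive <- n - n_deaths
  if (max(reference$count_with - reference$deaths_after) > n_alive) {
    cn_validation_error("not enough surviving rows for the carrier counts")
  }
  if (sum(reference$deaths_after) < n_deaths ||
      sum(reference$count_with - reference$deaths_after) < n_alive) {
    cn_validation_error(
      "carrier slots cannot cover every row with a complication")
  }
  catalog <- variable_catalog(c(reference$variable, "death"),
                              outcome = "death")
  values <- matrix(0L, nrow = n, ncol = length(catalog$names),
                   dimnames = list(NULL, catalog$names))
  values[seq_len(n_deaths), "death"] <- 1L
  # Round-robin pointers ensure every death row and every surviving row
  # receives at least one complication (total slots exceed the row counts).
  p_dead <- 0L
  p_alive <- 0L
  for (i in seq_len(nrow(reference))) {
    v <- reference$variable[i]
    d <- reference$deaths_after[i]
    s <- reference$count_with[i] - d
    if (d > 0L) {
      rows <- ((p_dead + seq_len(d) - 1L) %% n_deaths) + 1L
      values[rows, v] <- 1L
      p_dead <- (p_dead + d) %% n_deaths
    }
    if (s > 0L) {
      rows <- n_deaths + ((p_alive + seq_len(s) - 1L) %% n_alive) + 1L
      values[rows, v] <- 1L
      p_alive <- (p_alive + s) %% n_alive
    }
  }
  cohort_matrix(values, catalog = catalog)
}
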