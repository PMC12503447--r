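#' Conditional probability table for one binary node
#'
#' One probability P(node = 1 | parent configuration) per configuration of
#' the parents, indexed by the parents' joint binary assignment. The
#' configuration index of a row is `1 + sum(value_j * 2^(k-j))` for parents
#' j = 1..k in stored order, i.e. row 1 is all-parents-0 and the last row is
#' all-parents-1 (the first parent is the most significant bit).
#'
#' @param node Node name.
#' @param parents Character vector of parent names (possibly empty).
#' @param p1 Numeric vector of length `2^length(parents)` of probabilities
#'   P(node = 1 | config).
#' @param support Optional integer vector of observation counts per
#'   configuration (defaults to NA: unknown, e.g. for hand-specified
#'   ground-truth tables).
#' @param unsupported Logical vector flagging configurations never observed
#'   at fit time (their probability is the uniform fallback 0.5).
#' @return Object of class `cond_table`.
#' @export
cond_table <- function(node, parents, p1, support = NULL,
                       unsupported = NULL) {
  k <- length(parents)
  ncfg <- 2L^k
  if (length(p1) != ncfg) {
    cn_validation_error(sprintf(
      "node '%s': table needs %d rows for %d parents, got %d",
      node, ncfg, k, length(p1)))
  }
  if (anyNA(p1) || any(p1 < 0 | p1 > 1)) {
    cn_validation_error(sprintf(
      "node '%s': probabilities must lie in [0, 1]", node))
  }
  structure(list(node = node,
                 parents = as.character(parents),
                 p1 = as.numeric(p1),
                 support = support %||% rep(NA_integer_, ncfg),
                 unsupported = unsupported %||% rep(FALSE, ncfg)),
            class = "cond_table")
}

#' @export
print.cond_table <- function(x, ...) {
  k <- length(x$parents)
  cat(sprintf("CPT for '%s'", x$node))
  if (k > 0L) cat(" | ", paste(x$parents, collapse = ", "), sep = "")
  cat("\n")
  cfg <- config_grid(k)
  df <- data.frame(cfg, p1 = round(x$p1, 4), n = x$support)
  if (k > 0L) names(df)[seq_len(k)] <- x$parents
  print(df, row.names = FALSE)
  invisible(x)
}

# All parent configurations in index order as a 0/1 matrix (2^k x k);
# first parent = most significant bit, matching encode_config().
config_grid <- function(k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  idx <- 0:(2L^k - 1L)
  out <- sapply(seq_len(k), function(j) bitwAnd(idx %/% 2L^(k - j), 1L))
  matrix(as.integer(out), ncol = k)
}

#' Discrete Bayesian network
#'
#' A DAG plus one [cond_table()] per node; their product defines a joint
#' distribution over all 2^V binary states.
#'
#' @param dag A `dag_structure`.
#' @param tables Named list of `cond_table`s, one per node, whose parent
#'   lists agree with the DAG.
#' @return Object of class `discrete_bn`.
#' @export
discrete_bn <- function(dag, tables) {
  stopifnot(inherits(dag, "dag_structure"))
  if (!setequal(names(tables), dag$nodes)) {
    cn_validation_error("tables must be named by the DAG nodes")
  }
  for (v in dag$nodes) {
    tb <- tables[[v]]
    if (!inherits(tb, "cond_table") || !identical(tb$node, v) ||
        !setequal(tb$parents, dag_parents(dag, v))) {
      cn_validation_error(sprintf(
        "table for '%s' does not match its DAG parents", v))
    }
  }
  structure(list(dag = dag, tables = tables[dag$nodes]),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d arcs\n",
              length(x$dag$nodes), nrow(x$dag$arcs)))
  npar <- sum(vapply(x$tables, function(t) length(t$p1), numeric(1)))
  cat(sprintf("  %d conditional probabilities\n", npar))
  invisible(x)
}

#' Maximum-likelihood estimation of conditional probability tables
#'
#' For each node and each configuration of its DAG parents, estimates
#' P(node = 1 | config) = (n1 + alpha) / (n + 2 alpha) from the cohort,
#' where n is the number of patients in that configuration and n1 those
#' with the complication. `alpha = 0` (the default) is the pure maximum
#' likelihood estimate; configurations never observed at `alpha = 0` get
#' the uniform value 0.5 and are flagged `unsupported` so downstream
#' reports can annotate low-evidence probabilities.
#'
#' @param dag A `dag_structure` matching the cohort catalog.
#' @param cohort A `cohort_matrix`.
#' @param alpha Non-negative smoothing pseudocount (per node state).
#' @return A [discrete_bn()] whose tables carry per-configuration support
#'   counts.
#' @export
fit_cpts <- function(dag, cohort, alpha = 0) {
  stopifnot(inherits(dag, "dag_structure"), inherits(cohort, "cohort_matrix"))
  if (!setequal(dag$nodes, cohort$catalog$names)) {
    cn_validation_error("DAG nodes and cohort columns do not match")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    cn_validation_error("alpha must be a non-negative number")
  }
  values <- cohort$values
  tables <- lapply(dag$nodes, function(v) {
    parents <- sort(dag_parents(dag, v))
    k <- length(parents)
    ncfg <- 2L^k
    idx <- encode_config(values, parents) * 2L + values[, v] + 1L
    counts <- tabulate(idx, nbins = 2L * ncfg)
    n0 <- counts[seq(1L, 2L * ncfg, by = 2L)]
    n1 <- counts[seq(2L, 2L * ncfg, by = 2L)]
    n <- n0 + n1
    p1 <- (n1 + alpha) / (n + 2 * alpha)
    unsupported <- n == 0L
    p1[unsupported & alpha == 0] <- 0.5
    p1[is.na(p1)] <- 0.5  # n = 0 with alpha = 0 gives 0/0
    cond_table(v, parents, p1, support = as.integer(n),
               unsupported = unsupported)
  })
  names(tables) <- dag$nodes
  discrete_bn(dag, tables)
}

#' Log-likelihood of a cohort under a fitted network
#'
#' Sum over patients of the log of the factored joint probability. If any
#' patient hits a zero-probability configuration the result is `-Inf` and
#' the offending (node, configuration) pairs are attached as the
#' `"zero_events"` attribute.
#'
#' @param bn A `discrete_bn`.
#' @param cohort A `cohort_matrix` over the same variables.
#' @return Numeric scalar (possibly `-Inf`).
#' @export
loglik <- function(bn, cohort) {
  stopifnot(inherits(bn, "discrete_bn"), inherits(cohort, "cohort_matrix"))
  if (!setequal(bn$dag$nodes, cohort$catalog$names)) {
    cn_validation_error("network nodes and cohort columns do not match")
  }
  values <- cohort$values
  total <- 0
  zeros <- character(0)
  for (v in bn$dag$nodes) {
    tb <- bn$tables[[v]]
    cfg <- encode_config(values, tb$parents) + 1L
    p <- ifelse(values[, v] == 1L, tb$p1[cfg], 1 - tb$p1[cfg])
    if (any(p == 0)) {
      bad <- unique(cfg[p == 0])
      zeros <- c(zeros, sprintf("%s | config %d", v, bad))
      total <- -Inf
      next
    }
    total <- total + sum(log(p))
  }
  if (length(zeros) > 0L) {
    attr(total, "zero_events") <- zeros
  }
  total
}
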