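# Decomposable network scores for binary data.
#
# Both scores decompose as a sum of per-node family terms, each a function
# of (node, parent set) only. The family log-likelihood is computed from the
# contingency table of the node against the joint parent configuration; the
# BIC penalty charges (log N)/2 per free parameter, one per configuration
# (binary nodes). Larger scores are better.

# Encode the joint parent configuration of each row as an integer in
# 0..2^k-1. cols is an integer matrix of 0/1 columns restricted to parents.
encode_config <- function(values, parents) {
  n <- nrow(values)
  cfg <- integer(n)
  for (p in parents) {
    cfg <- cfg * 2L + values[, p]
  }
  cfg
}

# Family log-likelihood and BIC for one node given a parent set.
# Returns the score contribution of the family.
family_score <- function(values, node, parents, type = "bic") {
  n <- nrow(values)
  k <- length(parents)
  ncfg <- bitwShiftL(1L, k)
  idx <- encode_config(values, parents) * 2L + values[, node] + 1L
  counts <- tabulate(idx, nbins = 2L * ncfg)
  n0 <- counts[seq(1L, 2L * ncfg, by = 2L)]
  n1 <- counts[seq(2L, 2L * ncfg, by = 2L)]
  ntot <- n0 + n1
  ll <- 0
  pos <- n1 > 0L & ntot > 0L
  if (any(pos)) ll <- ll + sum(n1[pos] * log(n1[pos] / ntot[pos]))
  pos <- n0 > 0L & ntot > 0L
  if (any(pos)) ll <- ll + sum(n0[pos] * log(n0[pos] / ntot[pos]))
  if (type == "bic") ll - log(n) / 2 * ncfg else ll
}

#' Score a network structure on cohort data
#'
#' Computes the decomposable network score used by [hill_climb()]: the sum
#' over nodes of the family log-likelihood, minus for `score = "bic"` a
#' penalty of (log N)/2 per free parameter (one per parent configuration of
#' a binary node). Larger is better.
#'
#' @param dag A `dag_structure` whose nodes match the cohort columns.
#' @param cohort A `cohort_matrix`.
#' @param score `"bic"` (default) or `"loglik"`.
#' @return Object of class `score_value`: list with `total`, named
#'   `per_node` vector, and the score `type`. `total == sum(per_node)`.
#' @export
score_network <- function(dag, cohort, score = c("bic", "loglik")) {
  score <- match.arg(score)
  stopifnot(inherits(dag, "dag_structure"), inherits(cohort, "cohort_matrix"))
  if (!setequal(dag$nodes, cohort$catalog$names)) {
    cn_validation_error("DAG nodes and cohort columns do not match")
  }
  per_node <- vapply(dag$nodes, function(v) {
    family_score(cohort$values, v, dag_parents(dag, v), type = score)
  }, numeric(1))
  structure(list(total = sum(per_node), per_node = per_node, type = score),
            class = "score_value")
}

#' @export
print.score_value <- function(x, ...) {
  cat(sprintf("Network score (%s): %.4f\n", x$type, x$total))
  invisible(x)
}
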