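# Factor algebra over binary variables.
#
# A factor is a list(vars = character(), p = numeric(2^k)) where entry
# i corresponds to the assignment whose bits are
#   x_j = (i - 1) %/% 2^(j-1) %% 2   for vars[j]
# (vars[1] is the fastest-varying bit). All factors here are tiny
# (<= 13 binary variables), so dense vectors are the right representation.

make_factor <- function(vars, p) list(vars = vars, p = p)

# 0/1 assignment matrix for k binary variables, var 1 fastest-varying.
assignment_bits <- function(k) {
  n <- 2L^k
  idx <- 0:(n - 1L)
  out <- vapply(seq_len(k), function(j) bitwAnd(idx %/% 2L^(j - 1L), 1L),
                integer(n))
  matrix(as.integer(out), nrow = n, ncol = k)
}

factor_from_cpt <- function(tb) {
  # vars = (node, parents); build p over all assignments
  vars <- c(tb$node, tb$parents)
  k <- length(vars)
  bits <- assignment_bits(k)
  kpar <- length(tb$parents)
  if (kpar > 0L) {
    # parent bits are columns 2..k in cpt order; cpt row index uses parent 1
    # as most significant bit
    weights <- 2L^((kpar - 1L):0L)
    cfg <- as.vector(bits[, 2:k, drop = FALSE] %*% weights) + 1L
  } else {
    cfg <- rep(1L, 2L^k)
  }
  p1 <- tb$p1[cfg]
  p <- ifelse(bits[, 1L] == 1L, p1, 1 - p1)
  make_factor(vars, p)
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  k <- length(vars)
  bits <- assignment_bits(k)
  idx_of <- function(f) {
    if (length(f$vars) == 0L) return(rep(1L, 2L^k))
    pos <- match(f$vars, vars)
    w <- 2L^(seq_along(f$vars) - 1L)
    as.vector(bits[, pos, drop = FALSE] %*% w) + 1L
  }
  make_factor(vars, f1$p[idx_of(f1)] * f2$p[idx_of(f2)])
}

factor_marginalize <- function(f, var) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  k <- length(f$vars)
  bits <- assignment_bits(k)
  keep <- setdiff(seq_len(k), j)
  if (length(keep) == 0L) {
    return(make_factor(character(0), sum(f$p)))
  }
  w <- 2L^(seq_along(keep) - 1L)
  new_idx <- as.vector(bits[, keep, drop = FALSE] %*% w) + 1L
  p <- as.vector(rowsum(f$p, new_idx))
  make_factor(f$vars[keep], p)
}

factor_reduce <- function(f, var, value) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  k <- length(f$vars)
  bits <- assignment_bits(k)
  sel <- bits[, j] == value
  make_factor(f$vars[-j], f$p[sel])
}

#' Exact conditional probability query by variable elimination
#'
#' Computes P(target = 1 | evidence) exactly by sum-product variable
#' elimination over the network's factored joint. The elimination order is
#' chosen greedily: at each step the variable whose combined factor touches
#' the fewest other variables is summed out first (min-degree heuristic);
#' the result does not depend on this order.
#'
#' @param bn A `discrete_bn`.
#' @param target Name of the query variable.
#' @param evidence Named list or named vector of observed values in
#'   \{0, 1\}, e.g. `list(mods = 1)`; may be empty for a marginal.
#' @return P(target = 1 | evidence) as a number in \[0, 1\].
#' @examples
#' spec <- default_ground_truth()
#' bn <- as_discrete_bn(spec)
#' query(bn, "death", list(mods = 1))
#' @export
query <- function(bn, target, evidence = list()) {
  stopifnot(inherits(bn, "discrete_bn"))
  evidence <- validate_evidence(bn, evidence)
  if (!is.character(target) || length(target) != 1L ||
      !target %in% bn$dag$nodes) {
    cn_validation_error(sprintf("unknown target '%s'", target))
  }
  if (target %in% names(evidence)) {
    # self-evidence: P(target = 1 | ..., target = v) is v, provided the
    # evidence itself has positive probability
    p_ev <- joint_evidence_probability(bn, evidence)
    if (p_ev <= 0) {
      cn_validation_error("impossible evidence: P(evidence) = 0 under the model")
    }
    return(as.numeric(evidence[[target]] == 1L))
  }
  factors <- lapply(bn$tables, factor_from_cpt)
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v,
                      value = evidence[[v]])
  }
  elim <- setdiff(bn$dag$nodes, c(target, names(evidence)))
  while (length(elim) > 0L) {
    # min-degree: eliminate the variable whose combined factor is smallest
    degree <- vapply(elim, function(v) {
      touched <- unique(unlist(lapply(factors, function(f) {
        if (v %in% f$vars) f$vars else NULL
      })))
      length(touched)
    }, numeric(1))
    v <- elim[order(degree, elim)][1L]
    elim <- setdiff(elim, v)
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
  }
  final <- Reduce(factor_product, factors)
  stopifnot(identical(final$vars, target))  # all other vars were eliminated
  z <- sum(final$p)
  if (z <= 0) {
    cn_validation_error("impossible evidence: P(evidence) = 0 under the model")
  }
  final$p[2L] / z
}

validate_evidence <- function(bn, evidence) {
  if (length(evidence) == 0L) return(list())
  ev <- as.list(evidence)
  nm <- names(ev)
  if (is.null(nm) || any(!nzchar(nm))) {
    cn_validation_error("evidence must be a named list of 0/1 values")
  }
  if (anyDuplicated(nm)) {
    cn_validation_error("duplicate evidence variable(s)")
  }
  unknown <- setdiff(nm, bn$dag$nodes)
  if (length(unknown) > 0L) {
    cn_validation_error(sprintf("unknown evidence variable(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  vals <- unlist(ev)
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    cn_validation_error("evidence values must be 0 or 1")
  }
  stats::setNames(as.integer(vals), nm)
}

# P(evidence) by eliminating everything.
joint_evidence_probability <- function(bn, evidence) {
  factors <- lapply(bn$tables, factor_from_cpt)
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v, value = evidence[[v]])
  }
  for (v in setdiff(bn$dag$nodes, names(evidence))) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
  }
  prod(vapply(factors, function(f) sum(f$p), numeric(1)))
}

#' Posterior probability matrix for single-complication evidence
#'
#' For every ordered pair (target, evidence complication), the probability
#' that the target occurs given that the evidence complication occurred,
#' expressed as a percentage. Rows are all variables including the outcome
#' (so the last row is the death row); columns are the non-outcome
#' complications. Self-conditioning cells are `NA` (rendered as an em dash
#' in the printed table). Evidence with zero model probability flags the
#' whole column `NA` rather than failing.
#'
#' @param bn A fitted `discrete_bn` whose catalog outcome is known.
#' @param outcome Outcome variable name (default `"death"`).
#' @return Object of class `posterior_table`: list with `values` (matrix of
#'   percentages at full precision), and `queries` metadata.
#' @export
single_evidence_matrix <- function(bn, outcome = "death") {
  nodes <- bn$dag$nodes
  if (!outcome %in% nodes) {
    cn_validation_error(sprintf("unknown outcome '%s'", outcome))
  }
  ev_vars <- setdiff(nodes, outcome)
  targets <- c(ev_vars, outcome)
  values <- matrix(NA_real_, nrow = length(targets), ncol = length(ev_vars),
                   dimnames = list(targets, ev_vars))
  for (e in ev_vars) {
    ok <- tryCatch({
      for (t in targets) {
        if (t == e) next
        values[t, e] <- 100 * query(bn, t, stats::setNames(list(1L), e))
      }
      TRUE
    }, complnet_validation_error = function(err) FALSE)
    if (!ok) values[, e] <- NA_real_
  }
  structure(list(values = values,
                 queries = list(kind = "single_evidence", outcome = outcome)),
            class = "posterior_table")
}

#' Death probability under multi-complication evidence
#'
#' P(death = 1 | combo) for a list of evidence combinations, each a set of
#' complications observed to occur. Defaults to the canonical report
#' layout: each of the three common early complications (prolonged ICU
#' stay, increased chest tube drainage, prolonged ventilation) combined
#' with one or two of the severe complications.
#'
#' @param bn A fitted `discrete_bn`.
#' @param combos List of character vectors of complication names (each set
#'   to 1), or `NULL` for the default layout built by
#'   [default_death_combos()]. An empty list yields an empty table.
#' @param outcome Outcome variable name (default `"death"`).
#' @return A `posterior_table` with one row per combo: columns `combo`
#'   (label) and `p_death_pct`.
#' @export
multi_evidence_deaths <- function(bn, combos = NULL, outcome = "death") {
  nodes <- bn$dag$nodes
  if (!outcome %in% nodes) {
    cn_validation_error(sprintf("unknown outcome '%s'", outcome))
  }
  if (is.null(combos)) combos <- default_death_combos(bn, outcome = outcome)
  rows <- lapply(combos, function(combo) {
    combo <- as.character(combo)
    if (length(combo) < 1L) {
      cn_validation_error("each evidence combo needs at least one complication")
    }
    ev <- stats::setNames(as.list(rep(1L, length(combo))), combo)
    p <- tryCatch(100 * query(bn, outcome, ev),
                  complnet_validation_error = function(err) NA_real_)
    data.frame(combo = paste(combo, collapse = " + "),
               p_death_pct = p, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(combo = character(0), p_death_pct = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(values = tab,
                 queries = list(kind = "multi_evidence_death",
                                outcome = outcome, combos = combos)),
            class = "posterior_table")
}

#' Default multi-complication evidence layout
#'
#' Builds the canonical combination list: each common early complication
#' (those with marginal prevalence above 0.25 in the model) is paired with
#' each severe complication in the outcome's Markov blanket, alone and
#' together with each further severe complication.
#'
#' @param bn A `discrete_bn`.
#' @param outcome Outcome variable name.
#' @return List of character vectors of complication names.
#' @export
default_death_combos <- function(bn, outcome = "death") {
  nodes <- setdiff(bn$dag$nodes, outcome)
  marg <- vapply(nodes, function(v) query(bn, v), numeric(1))
  primaries <- nodes[marg > 0.25]
  severe <- setdiff(markov_blanket(bn$dag, outcome), primaries)
  combos <- list()
  for (p in primaries) {
    for (s in setdiff(severe, p)) {
      combos[[length(combos) + 1L]] <- c(p, s)
      for (s2 in setdiff(severe, c(p, s))) {
        if (s2 > s) combos[[length(combos) + 1L]] <- c(p, s, s2)
      }
    }
  }
  combos
}

#' Critical complications of the network
#'
#' The Markov blanket of the outcome node: the complications that render
#' death conditionally independent of everything else in the network. This
#' is the operational definition of the network's "critical complications".
#'
#' @param dag A `dag_structure`.
#' @param outcome Outcome node name (default `"death"`).
#' @return Sorted character vector of complication names.
#' @export
critical_nodes <- function(dag, outcome = "death") {
  markov_blanket(dag, outcome)
}

#' @export
print.posterior_table <- function(x, digits = 1, ...) {
  if (is.matrix(x$values)) {
    cat("Posterior probabilities (%), one column per evidence complication\n")
    shown <- round_half_up(x$values, digits)
    out <- format(shown, nsmall = digits)
    out[is.na(x$values)] <- "\u2014"
    print(out, quote = FALSE)
  } else {
    cat("P(death | complications) (%)\n")
    tab <- x$values
    tab$p_death_pct <- round_half_up(tab$p_death_pct, digits)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
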