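# Independent brute-force oracles. These deliberately avoid the package's
# factor/elimination code paths: probabilities come from direct per-state
# products over the full 2^V joint.

# All 2^V binary states as a matrix with named columns (node order of the
# DAG); row i encodes state i-1 with nodes[1] as the least significant bit.
enum_states <- function(nodes) {
  V <- length(nodes)
  n <- 2L^V
  idx <- 0:(n - 1L)
  states <- sapply(seq_len(V), function(j) (idx %/% 2L^(j - 1L)) %% 2L)
  states <- matrix(as.integer(states), nrow = n)
  colnames(states) <- nodes
  states
}

# Full joint distribution of a discrete_bn by enumeration.
enum_joint <- function(bn) {
  nodes <- bn$dag$nodes
  states <- enum_states(nodes)
  p <- rep(1, nrow(states))
  for (v in nodes) {
    tb <- bn$tables[[v]]
    cfg <- rep(0L, nrow(states))
    for (par in tb$parents) cfg <- cfg * 2L + states[, par]
    p1 <- tb$p1[cfg + 1L]
    p <- p * ifelse(states[, v] == 1L, p1, 1 - p1)
  }
  list(states = states, p = p)
}

# P(target = 1 | evidence) from the enumerated joint.
enum_query <- function(bn, target, evidence = list()) {
  joint <- enum_joint(bn)
  keep <- rep(TRUE, nrow(joint$states))
  for (v in names(evidence)) {
    keep <- keep & joint$states[, v] == evidence[[v]]
  }
  pz <- sum(joint$p[keep])
  sum(joint$p[keep & joint$states[, target] == 1L]) / pz
}

# Pairwise phi coefficients of a spec's exact joint.
enum_phi_pair <- function(bn, a, b) {
  joint <- enum_joint(bn)
  pa <- sum(joint$p[joint$states[, a] == 1L])
  pb <- sum(joint$p[joint$states[, b] == 1L])
  pab <- sum(joint$p[joint$states[, a] == 1L & joint$states[, b] == 1L])
  (pab - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
}

enum_query_marginal <- function(bn, v) enum_query(bn, v, list())

# Re-index a cond_table's p1 vector under a new parent ordering (the first
# parent is the most significant configuration bit in both orderings).
reorder_cpt <- function(tb, new_parents) {
  k <- length(new_parents)
  stopifnot(setequal(tb$parents, new_parents))
  if (k == 0L) return(tb$p1)
  idx <- 0:(2L^k - 1L)
  vals <- sapply(seq_len(k), function(j) (idx %/% 2L^(k - j)) %% 2L)
  vals <- matrix(vals, ncol = k, dimnames = list(NULL, new_parents))
  old_idx <- rep(0L, length(idx))
  ko <- length(tb$parents)
  for (j in seq_len(ko)) {
    old_idx <- old_idx * 2L + vals[, tb$parents[j]]
  }
  tb$p1[old_idx + 1L]
}

# Seeded sampling without touching the suite's RNG stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Markov blanket by naive scanning over the arc list.
brute_blanket <- function(dag, node) {
  arcs <- dag$arcs
  pa <- arcs[arcs[, 2L] == node, 1L]
  ch <- arcs[arcs[, 1L] == node, 2L]
  sp <- arcs[arcs[, 2L] %in% ch, 1L]
  sort(setdiff(unique(c(pa, ch, sp)), node))
}

# Every DAG on a set of labelled nodes, as a list of arc matrices
# (including the empty one). For 3 nodes this enumerates 25 DAGs.
all_dags <- function(nodes) {
  pairs <- t(combn(nodes, 2L))
  # each unordered pair is absent, forward, or backward
  choices <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (i in seq_len(nrow(choices))) {
    arcs <- NULL
    for (j in seq_len(nrow(pairs))) {
      c_ij <- choices[i, j]
      if (c_ij == 1) arcs <- rbind(arcs, pairs[j, ])
      if (c_ij == 2) arcs <- rbind(arcs, rev(pairs[j, ]))
    }
    dag <- tryCatch(dag_structure(nodes, arcs), error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1L]] <- dag
  }
  out
}

# Tiny cohort builder for hand-specified columns.
toy_cohort <- function(..., outcome = NULL) {
  cols <- list(...)
  values <- do.call(cbind, lapply(cols, as.integer))
  colnames(values) <- names(cols)
  outcome <- outcome %||% names(cols)[length(cols)]
  cohort_matrix(values, catalog = variable_catalog(names(cols), outcome))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand a 2x2 contingency table into two binary columns.
expand_2x2 <- function(n11, n10, n01, n00) {
  x <- c(rep(1L, n11 + n10), rep(0L, n01 + n00))
  y <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  cbind(x = x, y = y)
}

# Hand-built arc_confidence object for averaging tests.
make_conf <- function(df, nodes, n_replicates = 100L) {
  structure(df, class = c("arc_confidence", "data.frame"),
            nodes = nodes, n_replicates = n_replicates,
            blacklist = NULL)
}
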