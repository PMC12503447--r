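#' Score-based structure learning by greedy hill climbing
#'
#' Learns a DAG by local search over single-arc moves (add, delete,
#' reverse), accepting at each step the best strictly score-improving move
#' and stopping at a local optimum. Arcs in the blacklist are never added in
#' the forbidden direction, and no move may introduce a directed cycle. With
#' the default BIC score and independent columns the search returns the
#' empty graph, because the parameter penalty dominates.
#'
#' Ties between equally-improving moves are broken deterministically in
#' favour of the lexicographically smallest (source, target, move-type)
#' triple, so a run is fully reproducible. Optional random restarts perturb
#' the local optimum with a seeded set of random arc additions and re-climb,
#' keeping the best-scoring optimum found.
#'
#' @param cohort A `cohort_matrix`.
#' @param blacklist An [arc_blacklist()] or `NULL`.
#' @param score `"bic"` (default) or `"loglik"`.
#' @param restarts Number of random restarts (default 0: plain greedy
#'   ascent).
#' @param seed Integer seed for restart perturbations; unused when
#'   `restarts = 0`.
#' @return A `dag_structure` with attributes `score` (total network score of
#'   the optimum) and `score_type`.
#' @seealso [score_network()], [bootstrap_arcs()]
#' @export
hill_climb <- function(cohort, blacklist = NULL, score = c("bic", "loglik"),
                       restarts = 0, seed = NULL) {
  score <- match.arg(score)
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (!is_count(restarts)) cn_validation_error("restarts must be a count >= 0")
  values <- cohort$values
  nodes <- cohort$catalog$names
  snodes <- sort(nodes)
  V <- length(nodes)

  cache <- new.env(parent = emptyenv())
  fam <- function(node, parents) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score(values, node, parents, type = score)
      cache[[key]] <- val
    }
    val
  }

  bl <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    keep <- blacklist[, 1L] %in% nodes & blacklist[, 2L] %in% nodes
    blk <- blacklist[keep, , drop = FALSE]
    bl[blk] <- TRUE
  }

  eps <- 1e-8  # strict-improvement tolerance against float noise

  climb <- function(pars) {
    fscore <- vapply(nodes, function(v) fam(v, pars[[v]]), numeric(1))
    amat <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
    for (v in nodes) if (length(pars[[v]])) amat[pars[[v]], v] <- TRUE
    repeat {
      reach <- transitive_closure(amat)
      best_delta <- eps
      best <- NULL
      for (from in snodes) {
        for (to in snodes) {
          if (from == to) next
          if (!amat[from, to]) {
            # add from -> to
            if (!bl[from, to] && !reach[to, from] && !amat[to, from]) {
              delta <- fam(to, c(pars[[to]], from)) - fscore[[to]]
              if (delta > best_delta) {
                best_delta <- delta
                best <- list(type = "add", from = from, to = to)
              }
            }
          } else {
            # delete from -> to
            delta <- fam(to, setdiff(pars[[to]], from)) - fscore[[to]]
            if (delta > best_delta) {
              best_delta <- delta
              best <- list(type = "delete", from = from, to = to)
            }
            # reverse from -> to (only if the reversed arc is allowed and
            # no alternative from~>to path would close a cycle)
            if (!bl[to, from]) {
              amat[from, to] <- FALSE
              cyc <- reachable(amat, from, to)
              amat[from, to] <- TRUE
              if (!cyc) {
                delta <- (fam(to, setdiff(pars[[to]], from)) - fscore[[to]]) +
                  (fam(from, c(pars[[from]], to)) - fscore[[from]])
                if (delta > best_delta) {
                  best_delta <- delta
                  best <- list(type = "reverse", from = from, to = to)
                }
              }
            }
          }
        }
      }
      if (is.null(best)) break
      if (best$type == "add") {
        pars[[best$to]] <- c(pars[[best$to]], best$from)
        amat[best$from, best$to] <- TRUE
      } else if (best$type == "delete") {
        pars[[best$to]] <- setdiff(pars[[best$to]], best$from)
        amat[best$from, best$to] <- FALSE
      } else {
        pars[[best$to]] <- setdiff(pars[[best$to]], best$from)
        pars[[best$from]] <- c(pars[[best$from]], best$to)
        amat[best$from, best$to] <- FALSE
        amat[best$to, best$from] <- TRUE
      }
      for (v in unique(c(best$from, best$to))) {
        fscore[[v]] <- fam(v, pars[[v]])
      }
    }
    list(pars = pars, total = sum(fscore))
  }

  empty <- stats::setNames(rep(list(character(0)), V), nodes)
  result <- climb(empty)

  if (restarts > 0) {
    with_seed(seed %||% 0L, {
      for (r in seq_len(restarts)) {
        pars <- perturb_parents(result$pars, nodes, bl)
        cand <- climb(pars)
        if (cand$total > result$total + eps) result <- cand
      }
    })
  }

  arcs <- do.call(rbind, lapply(nodes, function(v) {
    if (length(result$pars[[v]]) == 0L) return(NULL)
    cbind(from = result$pars[[v]], to = v)
  }))
  dag <- dag_structure(nodes, arcs)
  attr(dag, "score") <- result$total
  attr(dag, "score_type") <- score
  dag
}

# Boolean transitive closure (paths of length >= 1) by repeated squaring.
transitive_closure <- function(amat) {
  reach <- amat
  repeat {
    nxt <- reach | ((reach %*% amat) > 0)
    if (identical(nxt, reach)) return(reach)
    reach <- nxt
  }
}

# DFS reachability from -> to on a logical adjacency matrix.
reachable <- function(amat, from, to) {
  stack <- from
  seen <- stats::setNames(logical(nrow(amat)), rownames(amat))
  while (length(stack) > 0L) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[[cur]]) next
    seen[[cur]] <- TRUE
    ch <- rownames(amat)[amat[cur, ]]
    if (to %in% ch) return(TRUE)
    stack <- c(stack, ch[!seen[ch]])
  }
  FALSE
}

# Random-restart perturbation: attempt a handful of random legal additions.
perturb_parents <- function(pars, nodes, bl) {
  V <- length(nodes)
  amat <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
  for (v in nodes) if (length(pars[[v]])) amat[pars[[v]], v] <- TRUE
  n_try <- max(2L, V %/% 2L)
  for (i in seq_len(n_try)) {
    uv <- sample(nodes, 2L)
    u <- uv[1L]; v <- uv[2L]
    if (!amat[u, v] && !amat[v, u] && !bl[u, v]) {
      reach <- transitive_closure(amat)
      if (!reach[v, u]) {
        amat[u, v] <- TRUE
        pars[[v]] <- c(pars[[v]], u)
      }
    }
  }
  pars
}
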