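#' Directed acyclic graph over catalog variables
#'
#' @param nodes Character vector of node names (unique, non-empty).
#' @param arcs Two-column character matrix or data frame of directed arcs
#'   (`from`, `to`); may have zero rows for the empty graph.
#'
#' @return Object of class `dag_structure`: list with `nodes` and `arcs`
#'   (character matrix with columns `from`, `to`).
#' @examples
#' dag_structure(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' @export
dag_structure <- function(nodes, arcs = NULL) {
  if (!is.character(nodes) || length(nodes) < 1L || anyDuplicated(nodes)) {
    cn_validation_error("nodes must be unique non-empty names")
  }
  arcs <- normalize_arcs(arcs)
  if (nrow(arcs) > 0L) {
    unknown <- setdiff(c(arcs), nodes)
    if (length(unknown) > 0L) {
      cn_validation_error(sprintf("arc endpoint(s) not in node set: %s",
                                  paste(unique(unknown), collapse = ", ")))
    }
    if (any(arcs[, 1L] == arcs[, 2L])) {
      cn_validation_error("self-loops are not allowed")
    }
    key <- paste(arcs[, 1L], arcs[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      cn_validation_error("duplicate arcs are not allowed")
    }
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "dag_structure")
  if (is.null(topological_sort_or_null(g))) {
    cn_validation_error("arc set contains a directed cycle")
  }
  g
}

normalize_arcs <- function(arcs) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0L) ||
      (is.data.frame(arcs) && nrow(arcs) == 0L)) {
    arcs <- matrix(character(0), ncol = 2L)
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (!is.matrix(arcs) || ncol(arcs) != 2L || !is.character(arcs)) {
    cn_validation_error("arcs must be a 2-column character matrix (from, to)")
  }
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  arcs
}

#' Parents / children of a node
#' @param dag A `dag_structure`.
#' @param node Node name.
#' @return Character vector of adjacent node names.
#' @export
dag_parents <- function(dag, node) {
  unname(dag$arcs[dag$arcs[, 2L] == node, 1L])
}

#' @rdname dag_parents
#' @export
dag_children <- function(dag, node) {
  unname(dag$arcs[dag$arcs[, 1L] == node, 2L])
}

#' Deterministic topological ordering of a DAG
#'
#' Kahn's algorithm with a lexicographic tie-break among in-degree-zero
#' candidates, so the same DAG always yields the same order on every
#' platform (this order drives ancestral sampling, making seeds portable).
#'
#' @param dag A `dag_structure`.
#' @return Character vector: the nodes in topological order.
#' @export
topological_sort <- function(dag) {
  ord <- topological_sort_or_null(dag)
  if (is.null(ord)) cn_validation_error("graph contains a directed cycle")
  ord
}

topological_sort_or_null <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(dag$arcs) > 0L) {
    tab <- table(dag$arcs[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  remaining <- sort(nodes)
  out <- character(0)
  while (length(remaining) > 0L) {
    avail <- remaining[indeg[remaining] == 0L]
    if (length(avail) == 0L) return(NULL)  # cycle
    nxt <- avail[1L]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- dag$arcs[dag$arcs[, 1L] == nxt, 2L]
    indeg[ch] <- indeg[ch] - 1L
  }
  out
}

# TRUE if a directed path from -> to exists (DFS on adjacency lists).
has_directed_path <- function(arcs, from, to) {
  if (from == to) return(TRUE)
  if (nrow(arcs) == 0L) return(FALSE)
  stack <- from
  seen <- character(0)
  while (length(stack) > 0L) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    ch <- arcs[arcs[, 1L] == cur, 2L]
    if (to %in% ch) return(TRUE)
    stack <- c(stack, setdiff(ch, seen))
  }
  FALSE
}

# Return the arcs of one directed cycle as a 2-column matrix, or NULL.
find_directed_cycle <- function(nodes, arcs) {
  if (nrow(arcs) == 0L) return(NULL)
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  dfs <- function(v, path) {
    color[v] <<- 1L
    ch <- arcs[arcs[, 1L] == v, 2L]
    for (w in ch) {
      if (color[w] == 1L) {
        # back edge v->w closes a cycle: recover arcs along path w ... v, v->w
        cyc_nodes <- c(path[match(w, path):length(path)], v)
        return(cbind(from = cyc_nodes, to = c(cyc_nodes[-1L], w)))
      }
      if (color[w] == 0L) {
        res <- dfs(w, c(path, v))
        if (!is.null(res)) return(res)
      }
    }
    color[v] <<- 2L
    NULL
  }
  for (v in sort(nodes)) {
    if (color[v] == 0L) {
      res <- dfs(v, character(0))
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents (spouses), excluding
#' the node itself. Conditioning on the blanket renders the node independent
#' of the rest of the network; the blanket of the death node is how the
#' network's "critical complications" are identified.
#'
#' @param dag A `dag_structure`.
#' @param node Node name.
#' @return Character vector of blanket members (sorted).
#' @examples
#' g <- dag_structure(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' markov_blanket(g, "b")  # a and c
#' @export
markov_blanket <- function(dag, node) {
  if (!node %in% dag$nodes) {
    cn_validation_error(sprintf("unknown node '%s'", node))
  }
  pa <- dag_parents(dag, node)
  ch <- dag_children(dag, node)
  spouses <- unlist(lapply(ch, function(c) dag_parents(dag, c)))
  sort(setdiff(unique(c(pa, ch, spouses)), node))
}

#' @export
print.dag_structure <- function(x, ...) {
  cat(sprintf("DAG: %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs) > 0L) {
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L]), sep = "\n")
  }
  invisible(x)
}

#' Arc blacklist
#'
#' Set of forbidden directed arcs for structure learning. The default for a
#' catalog forbids every arc out of the outcome node: death cannot cause a
#' complication.
#'
#' @param forbidden Two-column character matrix/data frame of forbidden arcs,
#'   or `NULL` for none.
#' @param catalog Optional [variable_catalog()]; when supplied, arcs from the
#'   outcome to every other variable are added to the blacklist.
#' @return Object of class `arc_blacklist` (2-column character matrix).
#' @export
arc_blacklist <- function(forbidden = NULL, catalog = NULL) {
  forbidden <- normalize_arcs(forbidden)
  if (!is.null(catalog)) {
    others <- complication_names(catalog)
    forbidden <- rbind(forbidden,
                       cbind(from = rep(catalog$outcome, length(others)),
                             to = others))
  }
  forbidden <- unique(forbidden)
  structure(forbidden, class = c("arc_blacklist", class(forbidden)))
}

is_blacklisted <- function(blacklist, from, to) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(FALSE)
  any(blacklist[, 1L] == from & blacklist[, 2L] == to)
}

#' Export a DAG in Graphviz DOT format
#'
#' @param dag A `dag_structure`.
#' @param path Optional file to write to.
#' @return The DOT source as a character scalar (invisibly if written).
#' @export
to_dot <- function(dag, path = NULL) {
  lines <- c("digraph complications {",
             "  rankdir=TB;",
             sprintf("  \"%s\";", dag$nodes),
             if (nrow(dag$arcs) > 0L) {
               sprintf("  \"%s\" -> \"%s\";", dag$arcs[, 1L], dag$arcs[, 2L])
             },
             "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
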