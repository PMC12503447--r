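# JSON (de)serialization of networks, models and ground-truth specs.
#
# One schema serves all three artifacts:
#   {
#     "nodes": [...], "outcome": "death",
#     "arcs": [{"from", "to", "strength"?, "direction"?}, ...],
#     "cpts": [{"node", "parents", "table": [{"config", "p1", "n"}]}]?,
#     "n_patients"?, "seed"?, "config"?: {...}
#   }
# A structure-only network omits "cpts"; a ground-truth spec carries
# n_patients and seed.

bn_to_list <- function(dag, tables = NULL, outcome = NULL, conf = NULL,
                       config = NULL, n_patients = NULL, seed = NULL) {
  arcs <- lapply(seq_len(nrow(dag$arcs)), function(i) {
    a <- list(from = dag$arcs[i, 1L], to = dag$arcs[i, 2L])
    if (!is.null(conf)) {
      hit <- which((conf$from == a$from & conf$to == a$to) |
                     (conf$from == a$to & conf$to == a$from))
      if (length(hit) == 1L) {
        a$strength <- conf$strength[hit]
        a$direction <- if (conf$from[hit] == a$from) {
          conf$direction[hit]
        } else {
          1 - conf$direction[hit]
        }
      }
    }
    a
  })
  out <- list(nodes = dag$nodes, outcome = outcome, arcs = arcs)
  if (!is.null(tables)) {
    out$cpts <- lapply(unname(tables), function(tb) {
      grid <- config_grid(length(tb$parents))
      list(node = tb$node, parents = tb$parents,
           table = lapply(seq_along(tb$p1), function(i) {
             row <- list(config = as.integer(grid[i, ]),
                         p1 = tb$p1[i],
                         n = if (is.na(tb$support[i])) NULL else tb$support[i],
                         unsupported = if (tb$unsupported[i]) TRUE else NULL)
             row[!vapply(row, is.null, logical(1))]
           }))
    })
  }
  out$n_patients <- n_patients
  out$seed <- seed
  out$config <- config
  out[!vapply(out, is.null, logical(1))]
}

list_to_bn_parts <- function(lst) {
  nodes <- unlist(lst$nodes)
  arcs <- if (length(lst$arcs) > 0L) {
    do.call(rbind, lapply(lst$arcs, function(a) c(a$from, a$to)))
  } else {
    NULL
  }
  dag <- dag_structure(nodes, arcs)
  tables <- NULL
  if (!is.null(lst$cpts)) {
    tables <- lapply(lst$cpts, function(ct) {
      parents <- as.character(unlist(ct$parents))
      p1 <- vapply(ct$table, function(r) as.numeric(r$p1), numeric(1))
      support <- vapply(ct$table, function(r) {
        if (length(r$n) != 1L) NA_integer_ else as.integer(r$n)
      }, integer(1))
      unsupported <- vapply(ct$table, function(r) {
        isTRUE(r$unsupported)
      }, logical(1))
      cond_table(ct$node, parents, p1, support = support,
                 unsupported = unsupported)
    })
    names(tables) <- vapply(tables, `[[`, "", "node")
  }
  list(dag = dag, tables = tables, outcome = lst$outcome,
       n_patients = lst$n_patients, seed = lst$seed, config = lst$config)
}

write_json_file <- function(x, path) {
  ok <- tryCatch({
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    cn_io_error(sprintf("cannot write '%s': %s", path,
                        conditionMessage(ok)))
  }
  invisible(path)
}

read_json_file <- function(path) {
  if (!file.exists(path)) cn_io_error(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write / read a learned network structure
#'
#' Exports a DAG, optionally annotated with bootstrap arc strength and
#' direction probabilities and the learning configuration.
#'
#' @param dag A `dag_structure`.
#' @param path Destination JSON path.
#' @param conf Optional `arc_confidence` used to annotate arcs.
#' @param config Optional named list recorded verbatim under `config`.
#' @param outcome Optional outcome variable name.
#' @return The path (write) or a list with `dag`, `conf` annotations and
#'   `config` (read), invisibly for the writer.
#' @export
write_network <- function(dag, path, conf = NULL, config = NULL,
                          outcome = NULL) {
  stopifnot(inherits(dag, "dag_structure"))
  write_json_file(bn_to_list(dag, conf = conf, config = config,
                             outcome = outcome), path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  parts <- list_to_bn_parts(read_json_file(path))
  parts[c("dag", "outcome", "config")]
}

#' Write / read a fitted Bayesian-network model
#'
#' Serializes a `discrete_bn` (structure plus conditional probability
#' tables with per-configuration support counts) to JSON and back.
#' Probabilities survive the decimal round trip to about 15 significant
#' digits; support counts and flags exactly.
#'
#' @param bn A `discrete_bn`.
#' @param path JSON path.
#' @param outcome Outcome variable name stored alongside (default
#'   `"death"` when present among the nodes).
#' @param config Optional named list recorded under `config`.
#' @return The path (writer, invisibly); a `discrete_bn` with `outcome`
#'   and `config` attributes (reader).
#' @export
write_model <- function(bn, path, outcome = NULL, config = NULL) {
  stopifnot(inherits(bn, "discrete_bn"))
  if (is.null(outcome) && "death" %in% bn$dag$nodes) outcome <- "death"
  write_json_file(bn_to_list(bn$dag, tables = bn$tables, outcome = outcome,
                             config = config), path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  parts <- list_to_bn_parts(read_json_file(path))
  if (is.null(parts$tables)) {
    cn_format_error("model file has no conditional probability tables")
  }
  bn <- discrete_bn(parts$dag, parts$tables)
  attr(bn, "outcome") <- parts$outcome
  attr(bn, "config") <- parts$config
  bn
}

#' Write / read a ground-truth simulation spec
#'
#' Same schema as the fitted-model JSON, with the target cohort size and
#' seed attached, so a learned model can be re-used as a generator.
#'
#' @param spec A [ground_truth_spec()].
#' @param path JSON path.
#' @return The path (writer, invisibly); a `ground_truth_spec` (reader).
#' @export
write_ground_truth <- function(spec, path) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  write_json_file(bn_to_list(spec$dag, tables = spec$cpts,
                             outcome = spec$catalog$outcome,
                             n_patients = spec$n_patients,
                             seed = spec$seed), path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  parts <- list_to_bn_parts(read_json_file(path))
  if (is.null(parts$tables)) {
    cn_format_error("ground-truth file has no conditional probability tables")
  }
  outcome <- parts$outcome %||% "death"
  catalog <- variable_catalog(parts$dag$nodes, outcome = outcome)
  ground_truth_spec(catalog, parts$dag, parts$tables,
                    n_patients = parts$n_patients %||% 18585,
                    seed = parts$seed %||% 1)
}
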