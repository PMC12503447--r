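#' Bootstrap arc confidence by model averaging
#'
#' Draws `replicates` bootstrap resamples of the cohort (N rows with
#' replacement), learns a network on each with [hill_climb()], and tallies
#' for every unordered pair of variables how often an arc between them
#' appears (its *strength*) and, among those appearances, how often it is
#' oriented each way (its *direction probability*). Replicate seeds are
#' derived deterministically from the master seed (`seed + replicate`), so
#' any single replicate can be reproduced in isolation.
#'
#' @param cohort A `cohort_matrix`.
#' @param blacklist An [arc_blacklist()] or `NULL`.
#' @param replicates Number of bootstrap replicates (>= 1); 1000 in the
#'   canonical configuration.
#' @param seed Integer master seed.
#' @param score,restarts Passed to [hill_climb()].
#' @return Object of class `arc_confidence`: a data frame with one row per
#'   unordered pair ever selected, columns `from`, `to` (lexicographic
#'   order within the pair), `strength`, and `direction` = P(from -> to |
#'   pair present). Attribute `n_replicates` records the replicate count,
#'   `blacklist` the active blacklist.
#' @export
bootstrap_arcs <- function(cohort, blacklist = NULL, replicates = 1000,
                           seed = 1, score = "bic", restarts = 0) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (!is_count(replicates) || replicates < 1) {
    cn_validation_error("replicates must be a count >= 1")
  }
  n <- n_patients(cohort)
  nodes <- cohort$catalog$names
  tally <- new.env(parent = emptyenv())  # key "u|v" ordered -> count
  for (r in seq_len(replicates)) {
    rows <- with_seed(seed + r, sample.int(n, n, replace = TRUE))
    boot <- cohort
    boot$values <- cohort$values[rows, , drop = FALSE]
    dag <- hill_climb(boot, blacklist = blacklist, score = score,
                      restarts = restarts, seed = seed + r)
    if (nrow(dag$arcs) > 0L) {
      keys <- paste(dag$arcs[, 1L], dag$arcs[, 2L], sep = "|")
      for (k in keys) tally[[k]] <- (tally[[k]] %||% 0L) + 1L
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L) {
    conf <- data.frame(from = character(0), to = character(0),
                       strength = numeric(0), direction = numeric(0),
                       stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "|", fixed = TRUE)
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 2L)
    cnt <- vapply(keys, function(k) tally[[k]], integer(1))
    # collapse to unordered pairs, canonical lexicographic (from < to)
    u <- ifelse(from < to, from, to)
    v <- ifelse(from < to, to, from)
    fwd <- ifelse(from < to, cnt, 0L)
    pair <- paste(u, v, sep = "|")
    agg_cnt <- tapply(cnt, pair, sum)
    agg_fwd <- tapply(fwd, pair, sum)
    pp <- strsplit(names(agg_cnt), "|", fixed = TRUE)
    conf <- data.frame(
      from = vapply(pp, `[`, "", 1L),
      to = vapply(pp, `[`, "", 2L),
      strength = as.numeric(agg_cnt) / replicates,
      direction = as.numeric(agg_fwd) / as.numeric(agg_cnt),
      stringsAsFactors = FALSE
    )
    conf <- conf[order(-conf$strength, conf$from, conf$to), , drop = FALSE]
    rownames(conf) <- NULL
  }
  structure(conf,
            class = c("arc_confidence", "data.frame"),
            n_replicates = as.integer(replicates),
            nodes = nodes,
            blacklist = blacklist)
}

#' Model-averaged network from bootstrap arc confidence
#'
#' Keeps every unordered pair whose strength exceeds `strength_min`, orients
#' it in its majority direction provided that direction's probability is at
#' least `direction_min`, and repairs any directed cycle among the kept
#' arcs by dropping the lowest-strength arc on the cycle until the result
#' is acyclic. An averaging run that filters out every arc yields a valid
#' empty DAG with a warning.
#'
#' @param conf An `arc_confidence` from [bootstrap_arcs()].
#' @param strength_min Strength threshold (arcs kept if strictly above);
#'   canonical value 0.75.
#' @param direction_min Minimum majority direction probability; canonical
#'   value 0.5.
#' @return A `dag_structure`; kept arcs carry `strength` and `direction`
#'   attributes (named by "from->to").
#' @export
averaged_network <- function(conf, strength_min = 0.75, direction_min = 0.5) {
  stopifnot(inherits(conf, "arc_confidence"))
  if (!is_probability(strength_min) || !is_probability(direction_min)) {
    cn_validation_error("thresholds must be probabilities in [0, 1]")
  }
  nodes <- attr(conf, "nodes")
  kept <- conf[conf$strength > strength_min, , drop = FALSE]
  arcs <- NULL
  strengths <- numeric(0)
  if (nrow(kept) > 0L) {
    maj_fwd <- kept$direction >= 0.5
    maj_prob <- ifelse(maj_fwd, kept$direction, 1 - kept$direction)
    ok <- maj_prob >= direction_min
    kept <- kept[ok, , drop = FALSE]
    maj_fwd <- maj_fwd[ok]
    if (nrow(kept) > 0L) {
      arcs <- cbind(from = ifelse(maj_fwd, kept$from, kept$to),
                    to = ifelse(maj_fwd, kept$to, kept$from))
      strengths <- kept$strength
    }
  }
  if (is.null(arcs) || nrow(arcs) == 0L) {
    warning("no arcs survive the strength/direction thresholds; ",
            "returning the empty network")
    return(dag_structure(nodes))
  }
  # cycle repair: while a directed cycle exists, drop its weakest arc
  repeat {
    cyc <- find_directed_cycle(nodes, arcs)
    if (is.null(cyc)) break
    cyc_key <- paste(cyc[, 1L], cyc[, 2L], sep = "|")
    all_key <- paste(arcs[, 1L], arcs[, 2L], sep = "|")
    on_cycle <- which(all_key %in% cyc_key)
    drop <- on_cycle[which.min(strengths[on_cycle])]
    arcs <- arcs[-drop, , drop = FALSE]
    strengths <- strengths[-drop]
  }
  dag <- dag_structure(nodes, arcs)
  attr(dag, "strength") <- stats::setNames(
    strengths, paste0(arcs[, 1L], "->", arcs[, 2L]))
  dag
}

#' @export
print.arc_confidence <- function(x, ...) {
  cat(sprintf("Bootstrap arc confidence (%d replicates, %d pairs)\n",
              attr(x, "n_replicates"), nrow(x)))
  NextMethod()
}
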