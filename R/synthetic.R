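#' Ground-truth specification for synthetic cohorts
#'
#' Bundles a catalog, a DAG, one conditional probability table per node, a
#' target cohort size and a seed: everything [sample_cohort()] needs to
#' draw reproducible patient-level binary matrices by ancestral sampling.
#'
#' @param catalog A [variable_catalog()].
#' @param dag A `dag_structure` over the catalog names.
#' @param cpts Named list of [cond_table()]s whose parent lists match the
#'   DAG.
#' @param n_patients Default cohort size for sampling.
#' @param seed Default integer seed.
#' @return Object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(catalog, dag, cpts, n_patients = 18585,
                              seed = 1) {
  stopifnot(inherits(catalog, "variable_catalog"))
  if (!setequal(dag$nodes, catalog$names)) {
    cn_validation_error("DAG nodes must match the catalog")
  }
  bn <- discrete_bn(dag, cpts)  # validates table/parent agreement + acyclicity
  if (!is_count(n_patients) || n_patients < 1) {
    cn_validation_error("n_patients must be a count >= 1")
  }
  structure(list(catalog = catalog, dag = bn$dag, cpts = bn$tables,
                 n_patients = as.integer(n_patients),
                 seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' View a ground-truth spec as a Bayesian network
#' @param x A `ground_truth_spec` (or a `discrete_bn`, returned as is).
#' @return A `discrete_bn`.
#' @export
as_discrete_bn <- function(x) {
  if (inherits(x, "discrete_bn")) return(x)
  if (inherits(x, "ground_truth_spec")) return(discrete_bn(x$dag, x$cpts))
  cn_validation_error("cannot coerce this object to a discrete_bn")
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf(
    "Ground-truth spec: %d nodes, %d arcs, n_patients = %d, seed = %d\n",
    length(x$catalog$names), nrow(x$dag$arcs), x$n_patients, x$seed))
  invisible(x)
}

#' Default 13-node ground-truth complication network
#'
#' A hand-specified Bayesian network over the [default_catalog()] variables
#' that emulates the qualitative structure of a perioperative complication
#' cohort: the three common early complications (chest tube drainage, ICU
#' stay, mechanical ventilation, marginal prevalence near 0.5) sit at the
#' top and feed, through reoperation, secondary intubation and renal
#' failure, into MODS and death; stroke is a near-independent rare node
#' whose only connection is its direct arc into death; death is a sink with
#' parents among the severe complications (secondary tracheal intubation,
#' stroke, postoperative renal failure, MODS) and no outgoing arcs. The
#' structure contains a v-structure (ventilation -> reoperation <-
#' tamponade) and a directed chain of length six ending in death.
#'
#' Marginal prevalences are anchored to the reference frequency table (see
#' [reference_counts()]): e.g. P(increased chest tube drainage) = 0.501,
#' rare complications between 0.005 and 0.03, and death conditional on MODS
#' above 0.9. Rare-node prevalences are kept at or above 0.005 so cohorts
#' of ~20,000 patients contain enough positives to estimate their tables.
#'
#' @param n_patients Default sample size attached to the spec.
#' @param seed Default seed attached to the spec.
#' @return A [ground_truth_spec()].
#' @examples
#' spec <- default_ground_truth()
#' query(as_discrete_bn(spec), "increased_chest_tube_drainage")  # ~0.501
#' @export
default_ground_truth <- function(n_patients = 18585, seed = 1) {
  catalog <- default_catalog()
  ctd <- "increased_chest_tube_drainage"
  icu <- "prolonged_icu_stays"
  pmv <- "prolonged_mechanical_ventilation"
  af <- "postoperative_af"
  mi <- "postoperative_mi"
  swi <- "sternal_wound_infections"
  pt <- "pericardial_tamponade"
  reop <- "reoperation"
  sti <- "secondary_tracheal_intubation"
  stroke <- "stroke"
  rf <- "postoperative_rf"
  mods <- "mods"
  death <- "death"

  arcs <- rbind(
    c(ctd, icu),
    c(icu, pmv),
    c(pmv, af),
    c(ctd, mi),
    c(ctd, pt),
    c(pmv, reop), c(pt, reop),
    c(reop, swi),
    c(pmv, sti),
    c(ctd, rf), c(sti, rf),
    c(rf, mods), c(sti, mods),
    c(sti, death), c(stroke, death), c(rf, death), c(mods, death)
  )
  dag <- dag_structure(catalog$names, arcs)

  # Parent order in each table is alphabetical (the fit_cpts convention);
  # the first parent is the most significant configuration bit.
  cpts <- list(
    cond_table(ctd, character(0), 0.501),
    cond_table(icu, ctd, c(0.38, 0.62)),
    cond_table(pmv, icu, c(0.315, 0.60)),
    cond_table(af, pmv, c(0.014, 0.040)),
    cond_table(mi, ctd, c(0.007, 0.013)),
    cond_table(stroke, character(0), 0.005),
    cond_table(pt, ctd, c(0.005, 0.013)),
    # (tamponade, ventilation): 00, 01, 10, 11
    cond_table(reop, sort(c(pt, pmv)), c(0.025, 0.085, 0.55, 0.65)),
    cond_table(swi, reop, c(0.0028, 0.040)),
    cond_table(sti, pmv, c(0.007, 0.055)),
    # (chest tube drainage, secondary intubation): 00, 01, 10, 11
    cond_table(rf, sort(c(ctd, sti)), c(0.010, 0.20, 0.025, 0.24)),
    # (renal failure, secondary intubation): 00, 01, 10, 11
    cond_table(mods, sort(c(rf, sti)), c(0.006, 0.08, 0.30, 0.45)),
    cond_table(death, sort(c(mods, rf, sti, stroke)),
               death_cpt_values())
  )
  names(cpts) <- vapply(cpts, `[[`, "", "node")
  ground_truth_spec(catalog, dag, cpts, n_patients = n_patients, seed = seed)
}

# Death risk as a monotone function of its four parents: with MODS present
# mortality starts at 0.92 and each further complication adds 0.02; without
# MODS the baseline 0.018 gains 0.38 for renal failure, 0.30 for secondary
# intubation and 0.40 for stroke, capped below the MODS floor. Parent order
# (alphabetical): mods, postoperative_rf, secondary_tracheal_intubation,
# stroke; mods is the most significant bit.
death_cpt_values <- function() {
  grid <- config_grid(4L)
  colnames(grid) <- c("mods", "rf", "sti", "stroke")
  apply(grid, 1L, function(g) {
    if (g[["mods"]] == 1L) {
      min(0.99, 0.92 + 0.02 * (g[["rf"]] + g[["sti"]] + g[["stroke"]]))
    } else {
      min(0.90, 0.018 + 0.38 * g[["rf"]] + 0.30 * g[["sti"]] +
            0.40 * g[["stroke"]])
    }
  })
}

#' Draw a synthetic cohort by ancestral sampling
#'
#' Samples each node in the deterministic topological order of the spec's
#' DAG (lexicographic tie-breaking), conditional on its already-sampled
#' parents. A single seeded generator drives the whole draw, so two calls
#' with the same seed return bitwise-identical matrices on any platform.
#'
#' @param spec A [ground_truth_spec()].
#' @param n Number of patients; defaults to `spec$n_patients`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A [cohort_matrix()] of 0/1 indicators.
#' @export
sample_cohort <- function(spec, n = NULL, seed = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  n <- as.integer(n %||% spec$n_patients)
  seed <- as.integer(seed %||% spec$seed)
  if (!is_count(n) || n < 1) cn_validation_error("n must be a count >= 1")
  order <- topological_sort(spec$dag)
  values <- matrix(0L, nrow = n, ncol = length(spec$catalog$names),
                   dimnames = list(NULL, spec$catalog$names))
  with_seed(seed, {
    for (v in order) {
      tb <- spec$cpts[[v]]
      cfg <- encode_config(values, tb$parents) + 1L
      values[, v] <- as.integer(stats::runif(n) < tb$p1[cfg])
    }
  })
  cohort_matrix(values, catalog = spec$catalog)
}

#' Summarize a sampled cohort against its generating spec
#'
#' Empirical per-variable prevalence and phi matrix, alongside the exact
#' marginals of the generating network (computed by variable elimination),
#' for convergence checks: as N grows the empirical prevalences approach
#' the exact ones.
#'
#' @param cohort A `cohort_matrix` whose columns match the spec catalog.
#' @param spec The generating [ground_truth_spec()].
#' @return Object of class `simulation_report`: list with
#'   `empirical_prevalence`, `exact_prevalence`, `empirical_phi`,
#'   `max_abs_error`, `n`, `seed_used`.
#' @export
summarize_sample <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_matrix"),
            inherits(spec, "ground_truth_spec"))
  if (!identical(cohort$catalog$names, spec$catalog$names)) {
    cn_validation_error("cohort columns do not match the spec catalog")
  }
  emp <- colMeans(cohort$values)
  bn <- as_discrete_bn(spec)
  exact <- vapply(spec$catalog$names, function(v) query(bn, v), numeric(1))
  phi <- phi_matrix(cohort)
  structure(list(empirical_prevalence = emp,
                 exact_prevalence = exact,
                 empirical_phi = phi,
                 max_abs_error = max(abs(emp - exact)),
                 n = n_patients(cohort),
                 seed_used = spec$seed),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("Simulation report (N = %d)\n", x$n))
  cat(sprintf("  max |empirical - exact| prevalence: %.4f\n",
              x$max_abs_error))
  invisible(x)
}

#' Random discrete Bayesian network
#'
#' Generates a random DAG (random topological order, each forward arc
#' included independently) with random conditional probabilities, useful
#' for stress-testing inference and learning against brute-force oracles.
#'
#' @param nodes Character vector of node names, or a count (names become
#'   `v01`, `v02`, ...).
#' @param p_arc Probability of including each forward arc.
#' @param max_parents Cap on the number of parents per node.
#' @param seed Integer seed.
#' @return A `discrete_bn`.
#' @export
random_bn <- function(nodes = 13, p_arc = 0.2, max_parents = 4, seed = 1) {
  if (is.numeric(nodes) && length(nodes) == 1L) {
    nodes <- sprintf("v%02d", seq_len(nodes))
  }
  with_seed(seed, {
    order <- sample(nodes)
    arcs <- NULL
    n_par <- stats::setNames(integer(length(nodes)), nodes)
    for (j in seq_along(order)) {
      for (i in seq_len(j - 1L)) {
        if (n_par[[order[j]]] < max_parents && stats::runif(1) < p_arc) {
          arcs <- rbind(arcs, c(order[i], order[j]))
          n_par[[order[j]]] <- n_par[[order[j]]] + 1L
        }
      }
    }
    dag <- dag_structure(nodes, arcs)
    cpts <- lapply(nodes, function(v) {
      parents <- sort(dag_parents(dag, v))
      ncfg <- 2L^length(parents)
      cond_table(v, parents, stats::runif(ncfg, 0.05, 0.95))
    })
    names(cpts) <- nodes
    discrete_bn(dag, cpts)
  })
}
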