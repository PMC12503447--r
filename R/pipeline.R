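#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end pipeline uses. Defaults
#' are the canonical analysis settings: learn on the with-complication
#' subset, BIC score, 1000 bootstrap replicates, strength threshold 0.75,
#' direction threshold 0.5, pure maximum-likelihood tables (alpha 0).
#'
#' @param input Path to a cohort CSV/TSV (or an in-memory
#'   `cohort_matrix`).
#' @param out_dir Output directory, created if missing.
#' @param delimiter Field separator of the input file.
#' @param filter `"with_complication"` (default) or `"all"`: cohort used
#'   for learning.
#' @param score `"bic"` or `"loglik"`.
#' @param replicates Bootstrap replicate count (>= 1).
#' @param strength_min,direction_min Model-averaging thresholds in [0, 1].
#' @param alpha CPT smoothing pseudocount (>= 0).
#' @param seed Master seed, recorded in every artifact.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir,
                            delimiter = ",",
                            filter = c("with_complication", "all"),
                            score = c("bic", "loglik"),
                            replicates = 1000,
                            strength_min = 0.75,
                            direction_min = 0.5,
                            alpha = 0,
                            seed = 1) {
  filter <- match.arg(filter)
  score <- match.arg(score)
  if (!is_count(replicates) || replicates < 1) {
    cn_validation_error("replicates must be a count >= 1")
  }
  if (!is_probability(strength_min) || !is_probability(direction_min)) {
    cn_validation_error("thresholds must lie in [0, 1]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    cn_validation_error("alpha must be a non-negative number")
  }
  structure(list(input = input, out_dir = out_dir, delimiter = delimiter,
                 filter = filter, score = score,
                 replicates = as.integer(replicates),
                 strength_min = strength_min,
                 direction_min = direction_min,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end complication-network pipeline
#'
#' filter -> describe -> learn -> fit -> report. Writes, under
#' `config$out_dir`: `marginals.tsv`, `cooccurrence.tsv`, `phi.tsv`,
#' `collinearity.tsv`, `network.json` (averaged structure with bootstrap
#' strengths), `model.json` (fitted tables), `table3.tsv`
#' (single-evidence posterior matrix), `table4.tsv` (multi-complication
#' death probabilities), `network.dot`, and `manifest.json` listing every
#' artifact with the full configuration and seed. Re-running with the same
#' configuration reproduces identical outputs. A stage failure aborts with
#' the stage name; artifacts written so far are marked incomplete in the
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # configuration as recorded inside network/model artifacts: the numeric
  # knobs only, so same-seed runs in different directories are identical
  cfg_record <- config[setdiff(names(config),
                               c("input", "out_dir", "delimiter"))]
  manifest <- list(config = config[setdiff(names(config), "input")],
                   input = if (is.character(config$input)) config$input
                           else "<in-memory cohort>",
                   artifacts = list(), complete = FALSE)
  stage <- "ingest"
  res <- tryCatch({
    cohort <- if (inherits(config$input, "cohort_matrix")) {
      config$input
    } else {
      read_cohort(config$input, delimiter = config$delimiter)
    }
    n_total <- n_patients(cohort)
    stage <- "filter"
    learn_cohort <- if (config$filter == "with_complication") {
      filter_any_complication(cohort)
    } else {
      cohort
    }
    message(sprintf("cohort: %d patients total, %d used for learning (%s)",
                    n_total, n_patients(learn_cohort), config$filter))

    stage <- "describe"
    paths <- list()
    marg <- marginal_summary(learn_cohort)
    paths$marginals <- file.path(config$out_dir, "marginals.tsv")
    utils::write.table(as.data.frame(marg), paths$marginals, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cooc <- cooccurrence_summary(learn_cohort)
    paths$cooccurrence <- file.path(config$out_dir, "cooccurrence.tsv")
    utils::write.table(
      data.frame(k = names(cooc$multiplicity_counts),
                 count = as.integer(cooc$multiplicity_counts)),
      paths$cooccurrence, sep = "\t", quote = FALSE, row.names = FALSE)
    phi <- phi_matrix(learn_cohort)
    paths$phi <- file.path(config$out_dir, "phi.tsv")
    utils::write.table(format(unclass(phi), digits = 10), paths$phi,
                       sep = "\t", quote = FALSE)
    coll <- collinearity_report(learn_cohort)
    paths$collinearity <- file.path(config$out_dir, "collinearity.tsv")
    utils::write.table(
      data.frame(eigenvalue = coll$eigenvalues,
                 condition_number = coll$condition_number,
                 flag_severe = coll$flag_severe),
      paths$collinearity, sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "learn"
    bl <- arc_blacklist(catalog = learn_cohort$catalog)
    message(sprintf("learning structure: %d bootstrap replicates, %s score",
                    config$replicates, config$score))
    conf <- bootstrap_arcs(learn_cohort, blacklist = bl,
                           replicates = config$replicates,
                           seed = config$seed, score = config$score)
    dag <- averaged_network(conf, strength_min = config$strength_min,
                            direction_min = config$direction_min)
    paths$network <- file.path(config$out_dir, "network.json")
    write_network(dag, paths$network, conf = conf,
                  outcome = learn_cohort$catalog$outcome,
                  config = cfg_record)
    paths$dot <- file.path(config$out_dir, "network.dot")
    to_dot(dag, paths$dot)

    stage <- "fit"
    bn <- fit_cpts(dag, learn_cohort, alpha = config$alpha)
    paths$model <- file.path(config$out_dir, "model.json")
    write_model(bn, paths$model, outcome = learn_cohort$catalog$outcome,
                config = cfg_record)

    stage <- "report"
    t3 <- single_evidence_matrix(bn, outcome = learn_cohort$catalog$outcome)
    paths$table3 <- file.path(config$out_dir, "table3.tsv")
    utils::write.table(round_half_up(t3$values, 1), paths$table3,
                       sep = "\t", quote = FALSE, na = "-")
    t4 <- multi_evidence_deaths(bn, outcome = learn_cohort$catalog$outcome)
    paths$table4 <- file.path(config$out_dir, "table4.tsv")
    t4df <- t4$values
    t4df$p_death_pct <- round_half_up(t4df$p_death_pct, 1)
    utils::write.table(t4df, paths$table4, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    manifest$artifacts <- lapply(paths, basename)
    manifest$n_patients_total <- n_total
    manifest$n_patients_learning <- n_patients(learn_cohort)
    manifest$n_arcs <- nrow(dag$arcs)
    manifest$critical_complications <-
      critical_nodes(dag, learn_cohort$catalog$outcome)
    manifest$complete <- TRUE
    manifest
  }, complnet_error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest
  })
  write_json_file(res, file.path(config$out_dir, "manifest.json"))
  if (!isTRUE(res$complete)) {
    cn_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    res$error), "complnet_pipeline_error")
  }
  invisible(res)
}
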