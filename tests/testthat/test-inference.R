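test_that("empty evidence returns marginals; parentless nodes their CPT", {
  bn <- random_bn(6, seed = 109)
  roots <- bn$dag$nodes[vapply(bn$dag$nodes, function(v) {
    length(dag_parents(bn$dag, v)) == 0L
  }, logical(1))]
  expect_gt(length(roots), 0L)
  for (v in roots) {
    expect_equal(query(bn, v), bn$tables[[v]]$p1, tolerance = 1e-12)
  }
})

test_that("self-evidence is certain and impossible evidence errors", {
  bn <- random_bn(5, seed = 113)
  v <- bn$dag$nodes[1L]
  expect_equal(query(bn, v, stats::setNames(list(1L), v)), 1.0)
  expect_equal(query(bn, v, stats::setNames(list(0L), v)), 0.0)

  # a deterministic node makes the opposite observation impossible
  tables <- list(a = cond_table("a", character(0), 1),
                 b = cond_table("b", character(0), 0.5))
  det <- discrete_bn(dag_structure(c("a", "b")), tables)
  expect_error(query(det, "b", list(a = 0)),
               class = "complnet_validation_error")
})

test_that("unknown names and bad evidence values are rejected", {
  bn <- random_bn(4, seed = 127)
  expect_error(query(bn, "nope"), class = "complnet_validation_error")
  expect_error(query(bn, bn$dag$nodes[1L], list(zz = 1)),
               class = "complnet_validation_error")
  expect_error(query(bn, bn$dag$nodes[1L],
                     stats::setNames(list(2), bn$dag$nodes[2L])),
               class = "complnet_validation_error")
})

test_that("variable elimination equals enumeration on random models", {
  for (seed in 1:10) {
    bn <- random_bn(13, p_arc = 0.2, seed = seed)
    nodes <- bn$dag$nodes
    ev_vars <- with_seed_local(seed, sample(nodes, sample(0:4, 1)))
    evidence <- stats::setNames(
      as.list(with_seed_local(seed + 1000, sample(0:1, length(ev_vars), TRUE))),
      ev_vars)
    target <- setdiff(nodes, ev_vars)[1L]
    expect_equal(query(bn, target, evidence),
                 enum_query(bn, target, evidence),
                 tolerance = 1e-10)
  }
})

test_that("the law of total probability holds to 1e-10", {
  bn <- random_bn(10, seed = 131)
  nodes <- bn$dag$nodes
  t <- nodes[3L]
  e <- nodes[7L]
  p_e <- enum_query_marginal(bn, e)
  lhs <- query(bn, t, stats::setNames(list(1L), e)) * p_e +
    query(bn, t, stats::setNames(list(0L), e)) * (1 - p_e)
  expect_equal(lhs, query(bn, t), tolerance = 1e-10)
})

test_that("conditioning beyond the Markov blanket changes nothing", {
  bn <- random_bn(9, p_arc = 0.25, seed = 137)
  nodes <- bn$dag$nodes
  for (t in nodes[1:3]) {
    blanket <- markov_blanket(bn$dag, t)
    outside <- setdiff(nodes, c(t, blanket))
    if (length(blanket) == 0L || length(outside) == 0L) next
    ev <- stats::setNames(as.list(rep(1L, length(blanket))), blanket)
    p_blanket <- tryCatch(query(bn, t, ev),
                          complnet_validation_error = function(e) NULL)
    if (is.null(p_blanket)) next  # blanket configuration impossible
    ev2 <- c(ev, stats::setNames(list(1L), outside[1L]))
    p_more <- tryCatch(query(bn, t, ev2),
                       complnet_validation_error = function(e) NULL)
    if (is.null(p_more)) next
    expect_equal(p_more, p_blanket, tolerance = 1e-10)
  }
})

test_that("independent nodes make every matrix cell the target marginal", {
  tables <- list(a = cond_table("a", character(0), 0.3),
                 b = cond_table("b", character(0), 0.6),
                 death = cond_table("death", character(0), 0.05))
  bn <- discrete_bn(dag_structure(c("a", "b", "death")), tables)
  tab <- single_evidence_matrix(bn)
  expect_equal(tab$values["a", "b"], 30)
  expect_equal(tab$values["b", "a"], 60)
  expect_equal(tab$values["death", "a"], 5)
  expect_equal(tab$values["death", "b"], 5)
  # self-conditioning cells are the undefined sentinel
  expect_true(is.na(tab$values["a", "a"]))
  expect_true(is.na(tab$values["b", "b"]))
})

test_that("matrix cells are calibrated against the generating model", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 50000, seed = 139)
  bn <- fit_cpts(spec$dag, cohort, alpha = 0)
  fitted_tab <- single_evidence_matrix(bn)
  truth <- as_discrete_bn(spec)
  # spot-check the death row and the strongest association against exact
  # queries on the ground truth: within 2 percentage points at this N
  for (e in c("mods", "postoperative_rf", "secondary_tracheal_intubation")) {
    expect_equal(fitted_tab$values["death", e],
                 100 * query(truth, "death", stats::setNames(list(1L), e)),
                 tolerance = 2, ignore_attr = TRUE)
  }
  expect_equal(fitted_tab$values["mods", "postoperative_rf"],
               100 * query(truth, "mods", list(postoperative_rf = 1L)),
               tolerance = 2, ignore_attr = TRUE)
})

test_that("multi-complication death table is consistent and monotone in MODS", {
  spec <- default_ground_truth()
  bn <- as_discrete_bn(spec)
  singles <- lapply(setdiff(bn$dag$nodes, "death"), function(v) v)
  t4 <- multi_evidence_deaths(bn, combos = singles)
  t3 <- single_evidence_matrix(bn)
  for (i in seq_along(singles)) {
    expect_equal(t4$values$p_death_pct[i],
                 t3$values["death", singles[[i]]], ignore_attr = TRUE)
  }
  # adding MODS evidence never lowers the death probability (the death
  # table is monotone in MODS by construction)
  combos <- list(c("postoperative_rf"),
                 c("postoperative_rf", "mods"),
                 c("secondary_tracheal_intubation"),
                 c("secondary_tracheal_intubation", "mods"))
  t4b <- multi_evidence_deaths(bn, combos = combos)
  expect_gte(t4b$values$p_death_pct[2L], t4b$values$p_death_pct[1L])
  expect_gte(t4b$values$p_death_pct[4L], t4b$values$p_death_pct[3L])

  empty <- multi_evidence_deaths(bn, combos = list())
  expect_equal(nrow(empty$values), 0L)
})

test_that("critical nodes are the outcome's Markov blanket", {
  dag <- dag_structure(c("rf", "death"), rbind(c("rf", "death")))
  expect_equal(critical_nodes(dag), "rf")
  dag2 <- dag_structure(c("a", "b", "death"),
                        rbind(c("a", "death"), c("b", "death")))
  expect_equal(critical_nodes(dag2), c("a", "b"))
  for (seed in 141:143) {
    bn <- random_bn(13, seed = seed)
    nodes <- bn$dag$nodes
    expect_equal(critical_nodes(bn$dag, outcome = nodes[5L]),
                 markov_blanket(bn$dag, nodes[5L]))
  }
})
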