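# Hand-computable BIC on a 4-row toy: two fair-coin columns, empty graph.
# Each family contributes 4 * log(0.5) for the log-likelihood and pays
# log(4)/2 for its single free parameter.
test_that("empty-graph BIC matches the closed form on a 4-row toy", {
  cohort <- toy_cohort(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  dag <- dag_structure(c("a", "b"))
  sc <- score_network(dag, cohort, score = "bic")
  per_family <- 4 * log(0.5) - log(4) / 2
  expect_equal(unname(sc$per_node), rep(per_family, 2))
  expect_equal(sc$total, 2 * per_family)
  ll <- score_network(dag, cohort, score = "loglik")
  expect_equal(ll$total, 8 * log(0.5))
})

test_that("an arc between identical columns increases BIC at n = 1000", {
  set.seed(47)
  x <- rbinom(1000, 1, 0.5)
  cohort <- cohort_matrix(cbind(a = x, b = x),
                          catalog = variable_catalog(c("a", "b"), "b"))
  empty <- score_network(dag_structure(c("a", "b")), cohort)
  with_arc <- score_network(
    dag_structure(c("a", "b"), rbind(c("a", "b"))), cohort)
  expect_gt(with_arc$total, empty$total)
})

test_that("the score is decomposable and order-invariant", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 300, seed = 53)
  sc <- score_network(spec$dag, cohort)
  expect_equal(sc$total, sum(sc$per_node))
  # same arc set in a different row order scores identically
  shuffled_arcs <- spec$dag$arcs[rev(seq_len(nrow(spec$dag$arcs))), ]
  sc2 <- score_network(dag_structure(spec$dag$nodes, shuffled_arcs), cohort)
  expect_equal(sc2$total, sc$total)
})

test_that("independent columns yield the empty DAG under BIC", {
  set.seed(59)
  values <- cbind(a = rbinom(10000, 1, 0.5), b = rbinom(10000, 1, 0.3),
                  c = rbinom(10000, 1, 0.7))
  cohort <- cohort_matrix(values,
                          catalog = variable_catalog(c("a", "b", "c"), "c"))
  dag <- hill_climb(cohort)
  expect_equal(nrow(dag$arcs), 0L)
})

test_that("hill climbing attains the exhaustive optimum on a 3-node chain", {
  catalog <- variable_catalog(c("a", "b", "c"), outcome = "c")
  dag <- dag_structure(catalog$names, rbind(c("a", "b"), c("b", "c")))
  cpts <- list(a = cond_table("a", character(0), 0.5),
               b = cond_table("b", "a", c(0.15, 0.85)),
               c = cond_table("c", "b", c(0.2, 0.8)))
  spec <- ground_truth_spec(catalog, dag, cpts, n_patients = 20000, seed = 61)
  cohort <- sample_cohort(spec)
  learned <- hill_climb(cohort)
  dags <- all_dags(catalog$names)
  expect_length(dags, 25L)  # all DAGs on three labelled nodes
  scores <- vapply(dags, function(d) score_network(d, cohort)$total,
                   numeric(1))
  expect_equal(attr(learned, "score"), max(scores), tolerance = 1e-9)
  # the learned skeleton is a-b, b-c with no a-c arc
  skel <- apply(learned$arcs, 1L, function(x) paste(sort(x), collapse = "~"))
  expect_setequal(skel, c("a~b", "b~c"))
})

test_that("the blacklist is respected and the score never drops below empty", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 4000, seed = 67)
  bl <- arc_blacklist(catalog = cohort$catalog)
  dag <- hill_climb(cohort, blacklist = bl)
  expect_false(any(dag$arcs[, 1L] == "death"))
  expect_no_error(topological_sort(dag))
  empty_score <- score_network(dag_structure(cohort$catalog$names), cohort)
  expect_gte(attr(dag, "score"), empty_score$total)
})

test_that("random restarts never return a worse optimum", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 2000, seed = 71)
  plain <- hill_climb(cohort)
  restarted <- hill_climb(cohort, restarts = 3, seed = 5)
  expect_gte(attr(restarted, "score"), attr(plain, "score") - 1e-9)
  restarted2 <- hill_climb(cohort, restarts = 3, seed = 5)
  expect_identical(restarted$arcs, restarted2$arcs)
})

test_that("single-replicate bootstrap tallies are 0/1 and directions sum to 1", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 1500, seed = 73)
  conf <- bootstrap_arcs(cohort, replicates = 1, seed = 2)
  expect_true(all(conf$strength %in% c(0, 1)))
  # direction(u->v) + direction(v->u) = 1 is encoded by a single row per
  # unordered pair carrying P(from->to); both orientations must be probs
  expect_true(all(conf$direction >= 0 & conf$direction <= 1))
})

test_that("a strong pairwise dependence is retained with high strength", {
  catalog <- variable_catalog(c("a", "b", "death"), outcome = "death")
  dag <- dag_structure(catalog$names, rbind(c("a", "b")))
  cpts <- list(a = cond_table("a", character(0), 0.5),
               b = cond_table("b", "a", c(0.1, 0.9)),
               death = cond_table("death", character(0), 0.02))
  spec <- ground_truth_spec(catalog, dag, cpts, n_patients = 5000, seed = 79)
  cohort <- sample_cohort(spec)
  conf <- bootstrap_arcs(cohort, replicates = 50, seed = 3)
  ab <- conf[conf$from == "a" & conf$to == "b", ]
  expect_equal(nrow(ab), 1L)
  expect_gt(ab$strength, 0.75)
})

test_that("averaging keeps, orients and thresholds pairs as specified", {
  nodes <- c("a", "b", "c")
  conf <- make_conf(data.frame(from = "a", to = "b", strength = 0.9,
                               direction = 0.2, stringsAsFactors = FALSE),
                    nodes)
  dag <- averaged_network(conf)
  expect_equal(unname(dag$arcs[1L, ]), c("b", "a"))  # majority direction

  weak <- make_conf(data.frame(from = "a", to = "b", strength = 0.6,
                               direction = 0.9, stringsAsFactors = FALSE),
                    nodes)
  expect_warning(dag2 <- averaged_network(weak, strength_min = 0.75))
  expect_equal(nrow(dag2$arcs), 0L)
})

test_that("cycle repair drops the weakest arc on the cycle", {
  nodes <- c("a", "b", "c")
  conf <- make_conf(data.frame(
    from = c("a", "b", "a"), to = c("b", "c", "c"),
    strength = c(0.9, 0.85, 0.8),
    # orientations a->b, b->c, c->a form a directed 3-cycle
    direction = c(1, 1, 0), stringsAsFactors = FALSE), nodes)
  dag <- averaged_network(conf)
  expect_equal(nrow(dag$arcs), 2L)
  kept <- paste(dag$arcs[, 1L], dag$arcs[, 2L], sep = "->")
  expect_setequal(kept, c("a->b", "b->c"))  # weakest arc c->a dropped
})

test_that("averaged_network is monotone in the strength threshold", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 1500, seed = 83)
  conf <- bootstrap_arcs(cohort, replicates = 20, seed = 4,
                         blacklist = arc_blacklist(catalog = cohort$catalog))
  arcs_at <- function(s) {
    d <- suppressWarnings(averaged_network(conf, strength_min = s))
    apply(d$arcs, 1L, paste, collapse = "->")
  }
  a50 <- arcs_at(0.5)
  a75 <- arcs_at(0.75)
  a90 <- arcs_at(0.9)
  expect_true(all(a75 %in% a50))
  expect_true(all(a90 %in% a75))
})

test_that("thresholds outside [0, 1] are rejected", {
  conf <- make_conf(data.frame(from = "a", to = "b", strength = 0.9,
                               direction = 1, stringsAsFactors = FALSE),
                    c("a", "b"))
  expect_error(averaged_network(conf, strength_min = 1.01),
               class = "complnet_validation_error")
})

test_that("markov blankets follow the parent/child/spouse rule", {
  chain <- dag_structure(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(markov_blanket(chain, "b"), c("a", "c"))
  vstruct <- dag_structure(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  expect_equal(markov_blanket(vstruct, "a"), c("b", "c"))
  expect_error(markov_blanket(chain, "zz"),
               class = "complnet_validation_error")
})

test_that("markov blankets match a brute-force scan on random DAGs", {
  for (seed in 1:5) {
    bn <- random_bn(13, p_arc = 0.25, seed = seed)
    for (v in bn$dag$nodes) {
      expect_equal(markov_blanket(bn$dag, v), brute_blanket(bn$dag, v))
    }
  }
})
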