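test_that("marginal percentages match an independent recount", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 500, seed = 23)
  marg <- marginal_summary(cohort, denominator = "all")
  comp <- setdiff(cohort$catalog$names, "death")
  for (i in seq_along(comp)) {
    col <- cohort$values[, comp[i]]
    expect_identical(marg$count_with[i], sum(col == 1L))
    expect_identical(marg$deaths_after[i],
                     sum(col == 1L & cohort$values[, "death"] == 1L))
  }
  expect_equal(marg$pct_with_raw, 100 * marg$count_with / 500)
})

test_that("death percentage handles the all-died and no-carrier edges", {
  cohort <- toy_cohort(stroke = c(1, 1, 0), mods = c(0, 0, 0),
                       death = c(1, 1, 0))
  marg <- marginal_summary(cohort, denominator = "all")
  expect_equal(marg$pct_death[marg$variable == "stroke"], 100.0)
  expect_true(is.na(marg$pct_death[marg$variable == "mods"]))
})

test_that("with-complication denominator counts rows with any complication", {
  cohort <- toy_cohort(a = c(1, 0, 0, 1), b = c(0, 0, 1, 1),
                       death = c(0, 1, 0, 0))
  marg <- marginal_summary(cohort)
  expect_equal(attr(marg, "denominator_n"), 3L)  # row 2 has death only
  expect_equal(marg$pct_with_raw[marg$variable == "a"], 100 * 2 / 3)
})

test_that("cooccurrence rates and multiplicity follow their definitions", {
  # three patients with complication sets {A}, {A,B}, {A,B,C}
  cohort <- toy_cohort(a = c(1, 1, 1), b = c(0, 1, 1), c = c(0, 0, 1),
                       death = c(0, 0, 0))
  cooc <- cooccurrence_summary(cohort)
  expect_equal(unname(cooc$cooccur_rate["a"]), 2 / 3)
  expect_equal(unname(cooc$cooccur_rate["b"]), 1)
  expect_equal(unname(cooc$multiplicity_counts[c("1", "2", "3")]),
               c(1L, 1L, 1L))
  expect_equal(sum(cooc$pattern_counts$count), 3L)
})

test_that("multiplicity histogram matches brute-force row sums", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 20000, seed = 29)
  cooc <- cooccurrence_summary(cohort)
  comp <- setdiff(cohort$catalog$names, "death")
  k <- rowSums(cohort$values[, comp])
  expect_equal(sum(cooc$multiplicity_counts), 20000L)
  for (kk in 0:4) {
    expect_equal(unname(cooc$multiplicity_counts[as.character(kk)]),
                 sum(k == kk))
  }
  frac_multi <- sum(k >= 2) / sum(k >= 1)
  got <- sum(cooc$multiplicity_counts[as.integer(names(cooc$multiplicity_counts)) >= 2]) /
    sum(cooc$multiplicity_counts[as.integer(names(cooc$multiplicity_counts)) >= 1])
  expect_equal(got, frac_multi)
})

test_that("phi matches hand values on 2x2 tables", {
  perfect <- expand_2x2(5, 0, 0, 5)
  cohort <- cohort_matrix(perfect,
                          catalog = variable_catalog(c("x", "y"), "y"))
  expect_equal(unclass(phi_matrix(cohort))["x", "y"], 1.0)

  indep <- expand_2x2(25, 25, 25, 25)
  cohort <- cohort_matrix(indep,
                          catalog = variable_catalog(c("x", "y"), "y"))
  expect_equal(unclass(phi_matrix(cohort))["x", "y"], 0.0)
})

test_that("phi equals the Pearson correlation of the binary columns", {
  cols <- expand_2x2(30, 10, 10, 50)
  cohort <- cohort_matrix(cols, catalog = variable_catalog(c("x", "y"), "y"))
  expect_equal(unclass(phi_matrix(cohort))["x", "y"],
               cor(cols[, "x"], cols[, "y"]), tolerance = 1e-12)
  # and on whole random cohorts (algebraic identity for 0/1 data)
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 3000, seed = 31)
  phi <- unclass(phi_matrix(cohort))
  expect_equal(phi, cor(cohort$values), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate columns yield flagged undefined entries", {
  cohort <- toy_cohort(a = c(1, 0, 1), b = c(0, 0, 0), death = c(0, 1, 0))
  phi <- phi_matrix(cohort)
  expect_true(is.na(unclass(phi)["a", "b"]))
  expect_true(is.na(unclass(phi)["b", "b"]))
  expect_gt(attr(phi, "n_undefined"), 0L)
  oracle <- suppressWarnings(cor(cohort$values))  # cor warns on zero variance
  expect_equal(unclass(phi)["a", "death"], oracle["a", "death"])
})

test_that("collinearity eigenvalues match an SVD-based computation", {
  spec <- default_ground_truth()
  cohort <- sample_cohort(spec, n = 1000, seed = 37)
  values <- cohort$values[, 1:5]
  sub <- cohort_matrix(values,
                       catalog = variable_catalog(colnames(values),
                                                  colnames(values)[5L]))
  rep <- collinearity_report(sub)
  # oracle: singular values of the standardized data matrix
  z <- scale(values)
  sv <- svd(z, nu = 0, nv = 0)$d
  ev_oracle <- sort(sv^2 / (nrow(values) - 1), decreasing = TRUE)
  expect_equal(rep$eigenvalues, ev_oracle, tolerance = 1e-8)
  expect_equal(rep$condition_number,
               sqrt(ev_oracle[1] / ev_oracle[length(ev_oracle)]),
               tolerance = 1e-8)
  expect_gte(rep$condition_number, 1)
})

test_that("near-independent columns give a condition number near 1", {
  set.seed(41)
  values <- matrix(rbinom(5 * 50000, 1, 0.5), ncol = 5,
                   dimnames = list(NULL, letters[1:5]))
  cohort <- cohort_matrix(values,
                          catalog = variable_catalog(letters[1:5], "e"))
  rep <- collinearity_report(cohort)
  expect_lt(rep$condition_number, 1.1)
  expect_false(rep$flag_severe)
})

test_that("a duplicated column is flagged as singular", {
  set.seed(43)
  x <- rbinom(200, 1, 0.4)
  values <- cbind(a = x, b = x, death = rbinom(200, 1, 0.1))
  cohort <- cohort_matrix(values,
                          catalog = variable_catalog(colnames(values), "death"))
  rep <- collinearity_report(cohort)
  expect_true(is.infinite(rep$condition_number))
  expect_true(rep$flag_severe)
})

test_that("the reference-count fixture has the printed column counts", {
  ref <- reference_counts()
  cohort <- cohort_from_marginals(ref)
  expect_equal(n_patients(cohort), 18585L)
  counts <- colSums(cohort$values)
  expect_equal(unname(counts[ref$variable]), ref$count_with)
  died <- cohort$values[, "death"] == 1L
  deaths <- colSums(cohort$values[died, ref$variable])
  expect_equal(unname(deaths), ref$deaths_after)
  # every patient has at least one complication, so the analysis
  # denominator is the full 18,585
  comp_sums <- rowSums(cohort$values[, ref$variable])
  expect_true(all(comp_sums >= 1L))
})
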