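test_that("Monte-Carlo precision reproduces the design half-widths", {
  # the study design quotes +/-0.6% on a 5% test size and +/-1.3% on a 50%
  # misclassification rate at 6000 replications
  expect_equal(eu_mc_precision(0.05, 6000), 1.96 * sqrt(0.05 * 0.95 / 6000))
  expect_equal(round(100 * eu_mc_precision(0.05, 6000), 1), 0.6)
  expect_equal(round(100 * eu_mc_precision(0.50, 6000), 1), 1.3)
  expect_lt(eu_mc_precision(0.5, 1e10), 1e-4)
  expect_error(eu_mc_precision(1.5, 100))
})

test_that("study tables carry complete accounting", {
  tab <- eu_rejection_study(eu_scenario(200), reps = 8, seed = 5)
  expect_s3_class(tab, "eu_study_table")
  expect_true(all(c("proportion", "mc_se", "n_valid", "n_dropped") %in%
                    names(tab)))
  expect_true(all(tab$n_valid + tab$n_dropped == 8))
  expect_true(all(tab$proportion >= 0 & tab$proportion <= 1))
  # alpha = 0 can reject nothing
  tab0 <- eu_rejection_study(eu_scenario(200), reps = 5, alpha = 0, seed = 5)
  expect_true(all(tab0$proportion == 0))
})

test_that("four-model assignment proportions partition the replicates", {
  tab <- eu_four_model_study(eu_scenario(400, beta_ep2 = 0.5), reps = 40,
                             criterion = "bic", seed = 11)
  expect_setequal(tab$strategy, c("null", "E", "U", "EU", "tie"))
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)
})

test_that("power rises with effect size and pre-specification ranks as expected", {
  scens <- list(e0.0 = eu_scenario(400),
                e0.5 = eu_scenario(400, beta_ep2 = 0.5),
                e1.0 = eu_scenario(400, beta_ep2 = 1))
  tab <- eu_rejection_study(scens,
                            strategies = c("bonferroni", "prespecified_E",
                                           "prespecified_U"),
                            reps = 250, seed = 404)
  bonf <- tab$proportion[tab$strategy == "bonferroni"]
  expect_true(all(diff(bonf) > 0))  # monotone power in effect size
  # with a genuine E effect: correctly pre-specified beats bonferroni,
  # incorrectly pre-specified loses to it
  at1 <- tab[tab$scenario_id == "e1.0", ]
  p <- setNames(at1$proportion, at1$strategy)
  expect_gt(p[["prespecified_E"]], p[["bonferroni"]])
  expect_gt(p[["bonferroni"]], p[["prespecified_U"]])
})

test_that("classification study output and evidence binning are coherent", {
  cl <- eu_classification_study(list(eu_scenario(400, beta_ep2 = 0.8)),
                                reps = 60, seed = 19)
  repl <- attr(cl, "replicates")
  expect_true(all(repl$delta_bic >= 0))
  expect_true(all(repl$correct == (repl$chosen == repl$truth), na.rm = TRUE))
  bins <- eu_bin_calibration(cl)
  expect_equal(nrow(bins), 4)
  expect_equal(sum(bins$n), sum(!is.na(repl$correct)))
  expect_equal(sum(bins$n_correct), sum(repl$correct, na.rm = TRUE))
  # scenarios with effects in both sub-models have no classification truth
  expect_error(
    eu_classification_study(eu_scenario(100, beta_up = 1, beta_ep2 = 1),
                            reps = 2, seed = 1),
    "both")
})

test_that("replicate seeding is stable and collision-free in practice", {
  s1 <- sapply(1:2000, function(i) eu_derive_seed(1, i))
  s2 <- sapply(1:2000, function(i) eu_derive_seed(2, i))
  expect_false(any(duplicated(s1)))
  expect_lt(length(intersect(s1, s2)) / 2000, 0.01)
  expect_identical(eu_derive_seed(7, 13), eu_derive_seed(7, 13))
})

test_that("the naive single-level logistic power comparator behaves", {
  # null calibration: rejection rate close to alpha
  p0 <- eu_naive_logistic_power(0, 400, 0.197, reps = 400, seed = 2)
  expect_lt(abs(p0$power - 0.05), 3 * eu_mc_precision(0.05, 400) / 1.96 + 1e-9)
  # increasing in n
  pa <- eu_naive_logistic_power(0.3, 200, 0.197, reps = 300, seed = 3)
  pb <- eu_naive_logistic_power(0.3, 1200, 0.197, reps = 300, seed = 3)
  expect_gt(pb$power, pa$power)
})

test_that("naive logistic power over-states EU power for a matched effect", {
  # same effect size and cycle count: the naive calculation ignores that
  # success also requires the other component, so it must come out higher
  naive <- eu_naive_logistic_power(0.4, 400, 0.197, reps = 300, seed = 8)
  tab <- eu_rejection_study(eu_scenario(400, beta_ep2 = 0.4),
                            strategies = "bonferroni", reps = 300,
                            seed = 8)
  expect_gt(naive$power, tab$proportion[1])
})
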