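test_that("likelihood-ratio test statistic, df and p-value are consistent", {
  b <- eu_spec(u = "U")
  full_spec <- eu_spec_add(b, "P", "u")
  # equal likelihoods: statistic 0, p = 1
  lr0 <- eu_lrtest(fake_fit(full_spec, -200), fake_fit(b, -200))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # the chi-square 95th percentiles map back to p = 0.05
  lr1 <- eu_lrtest(fake_fit(full_spec, -200 + 3.841459 / 2),
                   fake_fit(b, -200))
  expect_equal(lr1$df, 1)
  expect_equal(lr1$p_value, 0.05, tolerance = 1e-4)
  both_spec <- eu_spec_add(full_spec, "P2", "u")
  lr2 <- eu_lrtest(fake_fit(both_spec, -200 + 5.991465 / 2),
                   fake_fit(b, -200))
  expect_equal(lr2$df, 2)
  expect_equal(lr2$p_value, 0.05, tolerance = 1e-4)
  # a numerically lower "full" likelihood is clipped at zero
  lrc <- eu_lrtest(fake_fit(full_spec, -200.001), fake_fit(b, -200))
  expect_equal(lrc$statistic, 0)
})

test_that("lr test rejects non-nested or unconverged inputs", {
  a <- fake_fit(eu_spec(u = "A"), -10)
  b <- fake_fit(eu_spec(u = "B"), -9)
  expect_error(eu_lrtest(b, a), "not nested")
  big <- fake_fit(eu_spec(u = c("A", "B")), -8)
  expect_error(eu_lrtest(big, fake_fit(eu_spec(u = "A"), -10,
                                       converged = FALSE)),
               "converged")
  expect_error(eu_lrtest(a, a), "more parameters")
})

test_that("strategy decision rules follow their definitions", {
  run <- function(p_E, p_U, p_global, strategy, alpha = 0.05) {
    fits <- fake_strategy_fits(p_E, p_U, p_global)
    eu_test_variable(NULL, eu_spec(u = "U", e = c("Ep", "Ee")), "P",
                     strategy = strategy, alpha = alpha, fits = fits)
  }
  r <- run(0.03, 0.40, 0.10, "found_in_either")
  expect_true(r$significant)
  expect_equal(r$p_E, 0.03, tolerance = 1e-9)
  expect_false(run(0.03, 0.40, 0.10, "bonferroni")$significant) # 0.03 > 0.025
  expect_true(run(0.02, 0.40, 0.10, "bonferroni")$significant)
  expect_false(run(0.03, 0.40, 0.10, "found_in_both")$significant)
  expect_true(run(0.03, 0.04, 0.10, "found_in_both")$significant)
  expect_true(run(0.03, 0.04, 0.10, "found_in_either")$significant)
  expect_false(run(0.03, 0.04, 0.06, "global")$significant)
  expect_true(run(0.5, 0.5, 0.04, "global")$significant)
  expect_true(run(0.03, 0.40, 0.10, "prespecified_E")$significant)
  expect_false(run(0.03, 0.40, 0.10, "prespecified_U")$significant)
})

test_that("an unconverged required fit flags the result invalid", {
  fits <- fake_strategy_fits(0.01, 0.01)
  fits$E$converged <- FALSE
  r <- eu_test_variable(NULL, eu_spec(u = "U", e = c("Ep", "Ee")), "P",
                        strategy = "bonferroni", fits = fits)
  expect_false(r$valid)
  expect_true(is.na(r$significant))
})

test_that("testing an unknown or already-included variable errors", {
  d <- eu_simulate(eu_scenario(100, seed = 5))
  expect_error(eu_test_variable(d, base_spec(), "nope"), "cycle-level")
  expect_error(eu_test_variable(d, base_spec(), "U"), "already")
})

test_that("rejection sets are nested across strategies on real data", {
  # found_in_both and bonferroni rejections are subsets of found_in_either,
  # replicate by replicate
  spec0 <- base_spec()
  for (r in 1:25) {
    d <- eu_simulate(eu_scenario(400, beta_ep2 = 0.5 * (r %% 2),
                                 seed = 6000 + r))
    fits <- suppressWarnings(
      eu_variable_fits(d, spec0, "P", which = c("base", "E", "U")))
    if (!all(vapply(fits, function(f) f$converged, logical(1)))) next
    dec <- sapply(c("found_in_either", "found_in_both", "bonferroni"),
                  function(s) eu_test_variable(NULL, spec0, "P", s,
                                               fits = fits)$significant)
    if (dec[["found_in_both"]]) expect_true(dec[["found_in_either"]])
    if (dec[["bonferroni"]]) expect_true(dec[["found_in_either"]])
  }
})
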