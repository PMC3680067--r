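test_that("simulation is reproducible given a seed and leaves RNG alone", {
  s <- eu_scenario(500, seed = 123)
  d1 <- eu_simulate(s)
  d2 <- eu_simulate(s)
  expect_identical(d1$cycles, d2$cycles)
  expect_identical(d1$embryos, d2$embryos)
  d3 <- eu_simulate(s, seed = 124)
  expect_false(identical(d1$cycles$k_observed, d3$cycles$k_observed))
  # caller RNG state untouched
  set.seed(42); x1 <- runif(1)
  set.seed(42); invisible(eu_simulate(s)); x2 <- runif(1)
  expect_identical(x1, x2)
  expect_error(eu_simulate(eu_scenario(10)), "seed")
})

test_that("the transfer mix is fixed, not binomial", {
  for (n in c(10, 400, 1001)) {
    d <- eu_simulate(eu_scenario(n, seed = 9))
    expect_equal(sum(d$cycles$n_transferred == 2), round(0.7 * n))
    expect_equal(nrow(d$embryos), sum(d$cycles$n_transferred))
  }
  d0 <- eu_simulate(eu_scenario(50, prop_double = 0, seed = 2))
  expect_true(all(d0$cycles$n_transferred == 1))
})

test_that("covariates follow their specified laws", {
  d <- eu_simulate(eu_scenario(200000, seed = 7))
  cyc <- d$cycles
  tol <- 4 / sqrt(nrow(cyc))  # ~4 sigma on means of unit-scale variables
  expect_equal(mean(cyc$U), -0.5, tolerance = tol)
  expect_equal(sd(cyc$U), 0.5, tolerance = tol)
  expect_equal(mean(cyc$Ep), -0.1, tolerance = tol)
  expect_equal(sd(cyc$Ep), 0.3, tolerance = tol)
  expect_equal(mean(cyc$P), 0, tolerance = tol)
  expect_equal(sd(cyc$P), 1, tolerance = tol)
  expect_equal(mean(d$embryos$Ee), 3, tolerance = tol)
  expect_equal(sd(d$embryos$Ee), 0.6, tolerance = tol)
  # mean uterine receptivity E[logit^-1(0.1 + U)]: quadrature reference
  m_ref <- integrate(function(x) plogis(0.1 + x) * dnorm(x, -0.5, 0.5),
                     -Inf, Inf)$value
  expect_equal(m_ref, 0.407, tolerance = 2e-3)
  expect_equal(mean(plogis(0.1 + cyc$U)), m_ref, tolerance = 1e-3)
})

test_that("per-cycle Ee sharing is available as a switch", {
  d <- eu_simulate(eu_scenario(2000, ee_per_embryo = FALSE, seed = 5))
  emb <- d$embryos
  spread <- tapply(emb$Ee, emb$cycle_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  d2 <- eu_simulate(eu_scenario(2000, seed = 5))
  spread2 <- tapply(d2$embryos$Ee, d2$embryos$cycle_id,
                    function(x) diff(range(x)))
  expect_true(any(spread2 > 0))
})

test_that("observed k distribution matches the analytic cycle probabilities", {
  s <- eu_scenario(60000, beta_ep2 = 0.5, beta_up = 0.3, seed = 13)
  d <- eu_simulate(s)
  spec <- eu_spec(u = c("U", "P"), e = c("Ep", "P", "Ee"))
  theta <- eu_params(c(s$alpha_u, s$beta_u, s$beta_up),
                     c(s$alpha_e, s$beta_ep, s$beta_ep2, s$beta_ee),
                     spec = spec)
  pr <- eu_cycle_probabilities(d, spec, theta)
  dbl <- which(d$cycles$n_transferred == 2)
  # expected twin share among double transfers, averaged over covariates
  p2 <- vapply(dbl, function(i) {
    eu_kfold_probability(pr$u[[i]], pr$e[[i]], 2)
  }, numeric(1))
  emp <- mean(d$cycles$k_observed[dbl] == 2)
  expect_lt(abs(emp - mean(p2)),
            4 * sqrt(mean(p2) * (1 - mean(p2)) / length(dbl)))
  # and expected pregnancy rate overall
  p0 <- mapply(function(u, e) eu_kfold_probability(u, e, 0), pr$u, pr$e)
  expect_lt(abs(mean(d$cycles$k_observed >= 1) - mean(1 - p0)),
            4 * sqrt(mean(p0) * (1 - mean(p0)) / nrow(d$cycles)))
})

test_that("outcome rates are monotone in the covariate effects", {
  rates <- sapply(c(0, 0.5, 1), function(b) {
    eu_population_rates(eu_scenario(1, beta_up = b, beta_ep2 = b),
                        n_mc = 150000, seed = 17)$estimate
  })
  expect_true(all(diff(rates[1, ]) > 0))  # pregnancy rate
  expect_true(all(diff(rates[2, ]) > 0))  # twin rate
  # no receptive uterus, no pregnancies
  r0 <- eu_population_rates(eu_scenario(1, alpha_u = -40), n_mc = 20000,
                            seed = 3)
  expect_equal(r0$estimate[1], 0)
})
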