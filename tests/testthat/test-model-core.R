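test_that("sub-model probabilities are inverse-logit linear predictors", {
  # intercept-only, both intercepts zero: every probability is 1/2
  d <- toy_det_cycle()
  pr <- eu_cycle_probabilities(d, eu_spec(), eu_params(0, 0))
  expect_equal(unname(pr$u), 0.5)
  expect_equal(unname(pr$e[[1]]), c(0.5, 0.5))

  # patient covariate in U: u = logit^-1(0.1 + 1 * (-0.5)) = logit^-1(-0.4)
  d2 <- eu_dataset(data.frame(cycle_id = 1, n_transferred = 1,
                              k_observed = 0, U = -0.5))
  pr2 <- eu_cycle_probabilities(d2, eu_spec(u = "U"),
                                eu_params(c(0.1, 1), 0))
  expect_equal(unname(pr2$u), 1 / (1 + exp(0.4)), tolerance = 1e-12)
  expect_equal(round(unname(pr2$u), 4), 0.4013)

  # patient+embryo covariates in E: e = logit^-1(-3.66 - 0.1 + 3.0)
  d3 <- eu_dataset(
    data.frame(cycle_id = 1, n_transferred = 1, k_observed = 0, Ep = -0.1),
    data.frame(cycle_id = 1, embryo_index = 1, Ee = 3.0))
  pr3 <- eu_cycle_probabilities(d3, eu_spec(e = c("Ep", "Ee")),
                                eu_params(0, c(-3.66, 1, 1)))
  expect_equal(unname(pr3$e[[1]]), 1 / (1 + exp(0.76)), tolerance = 1e-12)
  expect_equal(round(unname(pr3$e[[1]]), 4), 0.3186)
})

test_that("a covariate missing from the dataset raises a schema error", {
  d <- toy_det_cycle()
  expect_error(
    eu_cycle_probabilities(d, eu_spec(u = "age"), eu_params(c(0, 1), 0)),
    "age")
  expect_error(eu_loglik(d, eu_spec(e = "grade"), eu_params(0, c(0, 1))),
               "grade")
})

test_that("k-fold pregnancy probability matches closed forms", {
  expect_equal(eu_kfold_probability(0.5, 0.5, 0), 0.75)
  expect_equal(eu_kfold_probability(1.0, c(1, 1), 2), 1.0)
  expect_equal(eu_kfold_probability(0.4, c(0.3, 0.2), 1),
               0.4 * (0.3 * 0.8 + 0.7 * 0.2))
  # normalization over k
  u <- 0.37; e <- c(0.1, 0.9)
  expect_equal(sum(sapply(0:2, function(k) eu_kfold_probability(u, e, k))),
               1, tolerance = 1e-12)
})

test_that("k-fold probability rejects out-of-range arguments", {
  expect_error(eu_kfold_probability(0.5, c(0.5, 0.5), 3), "k must be")
  expect_error(eu_kfold_probability(0.5, c(0.5, 0.5), -1), "k must be")
  expect_error(eu_kfold_probability(1.2, 0.5, 0), "u must be")
  expect_error(eu_kfold_probability(0.5, c(0.5, 1.4), 1), "e must be")
})

test_that("k-fold probability equals the exhaustive enumeration oracle", {
  set.seed(860214)
  for (rep in 1:100) {
    n <- sample(1:4, 1)
    u <- runif(1)
    e <- runif(n)
    for (k in 0:n) {
      expect_equal(eu_kfold_probability(u, e, k), oracle_kfold(u, e, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("subset enumeration and DP convolution agree", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    u <- runif(1); e <- runif(n); k <- sample(0:n, 1)
    expect_equal(eu_kfold_probability(u, e, k, cap = 10),
                 eu_kfold_probability(u, e, k, cap = 0),  # force DP path
                 tolerance = 1e-14)
  }
})

test_that("k-fold probability is symmetric in the embryos and monotone", {
  set.seed(4)
  for (rep in 1:20) {
    e <- runif(3); u <- runif(1); k <- sample(0:3, 1)
    expect_equal(eu_kfold_probability(u, e, k),
                 eu_kfold_probability(u, sample(e), k), tolerance = 1e-14)
  }
  # P_0 non-increasing in u and in each e_j
  p0 <- sapply(seq(0, 1, 0.1), function(u)
    eu_kfold_probability(u, c(0.3, 0.4), 0))
  expect_true(all(diff(p0) <= 1e-14))
  p0e <- sapply(seq(0, 1, 0.1), function(e1)
    eu_kfold_probability(0.6, c(e1, 0.4), 0))
  expect_true(all(diff(p0e) <= 1e-14))
})

test_that("log-likelihood matches closed form, is additive, matches oracle", {
  d <- toy_det_cycle(k = 0)
  ll <- eu_loglik(d, eu_spec(), eu_params(0, 0))
  expect_equal(ll, log(0.625), tolerance = 1e-12)

  spec <- base_spec()
  theta <- eu_params(c(0.1, 1), c(-3.66, 1, 1), spec = spec)
  d50 <- eu_simulate(eu_scenario(50, seed = 1234))
  # additivity over a split
  d_a <- eu_dataset(d50$cycles[1:20, ],
                    d50$embryos[d50$embryos$cycle_id %in% 1:20, ])
  d_b <- eu_dataset(d50$cycles[21:50, ],
                    d50$embryos[d50$embryos$cycle_id %in% 21:50, ])
  expect_equal(eu_loglik(d50, spec, theta),
               eu_loglik(d_a, spec, theta) + eu_loglik(d_b, spec, theta),
               tolerance = 1e-10)
  # agreement with the enumeration oracle
  expect_equal(eu_loglik(d50, spec, theta), oracle_loglik(d50, spec, theta),
               tolerance = 1e-10)
})

test_that("structurally impossible cycles are floored and reported", {
  # twin observed but embryo viability forced to ~0: probability underflows
  d <- eu_dataset(data.frame(cycle_id = c("a", "b"),
                             n_transferred = c(2, 2),
                             k_observed = c(2, 0)))
  expect_warning(ll <- eu_loglik(d, eu_spec(), eu_params(0, -800)),
                 "cycle_id a")
  expect_true(is.finite(ll))
  expect_identical(attr(ll, "bad_cycles"), "a")
})
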