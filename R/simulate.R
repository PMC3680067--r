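#' Define a simulation scenario for EU data
#'
#' Encodes the generating model used throughout the simulation studies:
#' \deqn{\mathrm{logit}\, u_i = \alpha_u + \beta_u U + \beta_{up} P, \qquad
#'   \mathrm{logit}\, e_{ij} = \alpha_e + \beta_{ep} E_p + \beta_{ee} E_e
#'   + \beta_{ep2} P.}
#' `U` and `Ep` are fixed cycle-level covariates, `Ee` a fixed embryo-level
#' covariate, and `P` a putative patient-level covariate whose effects
#' `beta_up` (through the uterus) and `beta_ep2` (through the embryos) are
#' the quantities under study. The default covariate laws
#' (`U ~ N(-0.5, 0.5^2)`, `Ep ~ N(-0.1, 0.3^2)`, `Ee ~ N(3, 0.6^2)`,
#' `P ~ N(0, 1)`), intercepts (`alpha_u = 0.1`, `alpha_e = -3.66`), unit
#' fixed-covariate coefficients and the 30% single / 70% double transfer
#' mix are calibrated to a large multi-centre UK IVF registry: with
#' `beta_up = beta_ep2 = 0` they reproduce an overall pregnancy rate of
#' about 19.7% and a twin rate of about 3.2% (4.6% among double
#' transfers).
#'
#' @param n_cycles number of treatment cycles.
#' @param beta_up effect of `P` in the uterus sub-model.
#' @param beta_ep2 effect of `P` in the embryo sub-model.
#' @param prop_double fraction of cycles with two embryos transferred; the
#'   count is fixed at `round(prop_double * n_cycles)`, not binomial.
#' @param alpha_u,alpha_e sub-model intercepts.
#' @param beta_u,beta_ep,beta_ee coefficients of the fixed covariates.
#' @param u_mean,u_sd,ep_mean,ep_sd,ee_mean,ee_sd,p_mean,p_sd covariate
#'   distribution parameters.
#' @param ee_per_embryo draw `Ee` independently for each embryo (default);
#'   `FALSE` draws one value per cycle shared by its embryos.
#' @param seed default seed used by [eu_simulate()].
#' @return An object of class `eu_scenario` (a list of the above).
#' @export
#' @examples
#' eu_scenario(n_cycles = 400, beta_ep2 = 0.5, seed = 1)
eu_scenario <- function(n_cycles, beta_up = 0, beta_ep2 = 0,
                        prop_double = 0.70,
                        alpha_u = 0.1, alpha_e = -3.66,
                        beta_u = 1, beta_ep = 1, beta_ee = 1,
                        u_mean = -0.5, u_sd = 0.5,
                        ep_mean = -0.1, ep_sd = 0.3,
                        ee_mean = 3, ee_sd = 0.6,
                        p_mean = 0, p_sd = 1,
                        ee_per_embryo = TRUE, seed = NULL) {
  stopifnot(n_cycles >= 1, prop_double >= 0, prop_double <= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 beta_up = beta_up, beta_ep2 = beta_ep2,
                 prop_double = prop_double,
                 alpha_u = alpha_u, alpha_e = alpha_e,
                 beta_u = beta_u, beta_ep = beta_ep, beta_ee = beta_ee,
                 u_mean = u_mean, u_sd = u_sd,
                 ep_mean = ep_mean, ep_sd = ep_sd,
                 ee_mean = ee_mean, ee_sd = ee_sd,
                 p_mean = p_mean, p_sd = p_sd,
                 ee_per_embryo = isTRUE(ee_per_embryo), seed = seed),
            class = "eu_scenario")
}

#' @export
print.eu_scenario <- function(x, ...) {
  cat("<eu_scenario> ", x$n_cycles, " cycles (",
      round(100 * (1 - x$prop_double)), "% SET / ",
      round(100 * x$prop_double), "% DET)\n", sep = "")
  cat("  logit(u) = ", x$alpha_u, " + ", x$beta_u, "*U + ",
      x$beta_up, "*P\n", sep = "")
  cat("  logit(e) = ", x$alpha_e, " + ", x$beta_ep, "*Ep + ",
      x$beta_ee, "*Ee + ", x$beta_ep2, "*P\n", sep = "")
  invisible(x)
}

#' Simulate an EU dataset from a scenario
#'
#' Per cycle, one value each of `U`, `Ep` and `P` is drawn from the
#' covariate laws, and `Ee` is drawn independently for each transferred
#' embryo. The linear predictors give `u_i` and `e_ij`; uterine receptivity
#' and per-embryo viability are realised as Bernoulli draws; the observed
#' implantation count is `k_i = receptive_i * sum_j(viable_ij)`. The mix of
#' single and double transfers is fixed at exactly
#' `round(prop_double * n_cycles)` double transfers, assigned to randomised
#' positions. Output is deterministic given the seed and leaves the
#' caller's RNG state untouched.
#'
#' @param scenario an `eu_scenario`.
#' @param seed integer seed; defaults to `scenario$seed`.
#' @return An `eu_data` object with cycle covariates `U`, `Ep`, `P` and
#'   embryo covariate `Ee`.
#' @export
#' @examples
#' d <- eu_simulate(eu_scenario(n_cycles = 200, seed = 42))
#' d
eu_simulate <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "eu_scenario"))
  if (is.null(seed)) {
    stop("a seed is required (in the scenario or as an argument)",
         call. = FALSE)
  }
  with_seed(seed, {
    s <- scenario
    n <- s$n_cycles
    n_double <- round(s$prop_double * n)
    n_tr <- sample(c(rep(1L, n - n_double), rep(2L, n_double)))

    U <- stats::rnorm(n, s$u_mean, s$u_sd)
    Ep <- stats::rnorm(n, s$ep_mean, s$ep_sd)
    P <- stats::rnorm(n, s$p_mean, s$p_sd)

    n_emb <- sum(n_tr)
    cyc_of_emb <- rep.int(seq_len(n), n_tr)
    if (s$ee_per_embryo) {
      Ee <- stats::rnorm(n_emb, s$ee_mean, s$ee_sd)
    } else {
      Ee <- stats::rnorm(n, s$ee_mean, s$ee_sd)[cyc_of_emb]
    }

    u <- stats::plogis(s$alpha_u + s$beta_u * U + s$beta_up * P)
    e <- stats::plogis(s$alpha_e + s$beta_ep * Ep[cyc_of_emb] +
                         s$beta_ee * Ee + s$beta_ep2 * P[cyc_of_emb])

    receptive <- stats::rbinom(n, 1L, u)
    viable <- stats::rbinom(n_emb, 1L, e)
    k <- receptive * as.integer(rowsum(viable, cyc_of_emb))

    emb_index <- sequence(n_tr)
    eu_dataset(
      cycles = data.frame(cycle_id = seq_len(n), n_transferred = n_tr,
                          k_observed = k, U = U, Ep = Ep, P = P),
      embryos = data.frame(cycle_id = cyc_of_emb, embryo_index = emb_index,
                           Ee = Ee))
  })
}

#' Monte-Carlo outcome rates of a scenario
#'
#' Estimates the overall pregnancy rate `P(k >= 1)`, the overall twin rate
#' `P(k = 2)` and the twin rate among double transfers
#' `P(k = 2 | n_transferred = 2)` by simulating a large cohort.
#'
#' @param scenario an `eu_scenario` (its `n_cycles` is ignored).
#' @param n_mc number of simulated cycles (at least 1e5 recommended).
#' @param seed integer seed.
#' @return A data frame with columns `rate` (name), `estimate` and `se`
#'   (binomial Monte-Carlo standard error).
#' @export
eu_population_rates <- function(scenario, n_mc = 5e5, seed = 1) {
  stopifnot(inherits(scenario, "eu_scenario"))
  s <- scenario
  s$n_cycles <- as.integer(n_mc)
  d <- eu_simulate(s, seed = seed)
  k <- d$cycles$k_observed
  dbl <- d$cycles$n_transferred == 2L
  est <- c(pregnancy = mean(k >= 1),
           twin = mean(k == 2),
           twin_double = if (any(dbl)) mean(k[dbl] == 2) else NA_real_)
  n <- c(n_mc, n_mc, sum(dbl))
  data.frame(rate = names(est), estimate = unname(est),
             se = sqrt(unname(est) * (1 - unname(est)) / n))
}
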