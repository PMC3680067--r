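#' Monte-Carlo precision of an estimated proportion
#'
#' Half-width of the two-sided 95% confidence interval of a proportion
#' estimated from `reps` independent replications:
#' `1.96 * sqrt(p * (1 - p) / reps)`. At 6000 replications this gives about
#' +/-0.6 percentage points on a 5% rejection rate and +/-1.3 points on a
#' 50% classification rate.
#'
#' @param p the proportion.
#' @param reps number of replications.
#' @return The half-width on the 0-1 scale.
#' @export
eu_mc_precision <- function(p, reps) {
  stopifnot(p >= 0, p <= 1, reps >= 1)
  1.96 * sqrt(p * (1 - p) / reps)
}

# The generating base model of the simulation design: fixed covariates
# U (uterus), Ep (patient-level, embryo sub-model) and Ee (embryo-level).
eu_base_spec <- function() eu_spec(u = "U", e = c("Ep", "Ee"))

as_scenario_list <- function(scenarios) {
  if (inherits(scenarios, "eu_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1,
            all(vapply(scenarios, inherits, logical(1), "eu_scenario")))
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    names(scenarios) <- vapply(seq_along(scenarios), function(i) {
      s <- scenarios[[i]]
      sprintf("s%02d_n%d_bup%g_bep%g", i, s$n_cycles, s$beta_up, s$beta_ep2)
    }, character(1))
  }
  scenarios
}

scenario_row <- function(id, s) {
  data.frame(scenario_id = id, n_cycles = s$n_cycles,
             beta_up = s$beta_up, beta_ep2 = s$beta_ep2,
             stringsAsFactors = FALSE)
}

#' Rejection-rate study: type-I error and power of the testing strategies
#'
#' For each scenario, simulates `reps` datasets and applies the requested
#' testing strategies for the patient-level variable `P` to every dataset,
#' sharing the fitted models across strategies within a replicate (paired
#' design, which removes between-strategy Monte-Carlo noise). Under a null
#' scenario (`beta_up = beta_ep2 = 0`) the rejection proportion estimates
#' the type-I error; otherwise it estimates power. Replicates in which any
#' required fit fails to converge are dropped and counted.
#'
#' @param scenarios an `eu_scenario` or list of them.
#' @param strategies character vector of strategies
#'   (see [eu_test_variable()]).
#' @param reps replications per scenario.
#' @param alpha nominal significance level.
#' @param seed base seed; each (scenario, replicate) pair derives its own
#'   reproducible sub-seed.
#' @param verbose print progress to stderr.
#' @return A data frame of class `eu_study_table` with one row per
#'   scenario x strategy: `scenario_id`, `n_cycles`, `beta_up`, `beta_ep2`,
#'   `metric` (`"rejection"`), `strategy`, `proportion`, `mc_se`,
#'   `n_valid`, `n_dropped`.
#' @export
eu_rejection_study <- function(scenarios,
                               strategies = c("found_in_either",
                                              "found_in_both", "global",
                                              "bonferroni",
                                              "prespecified_U",
                                              "prespecified_E"),
                               reps = 2000, alpha = 0.05, seed = 1,
                               verbose = FALSE) {
  scenarios <- as_scenario_list(scenarios)
  strategies <- match.arg(strategies, several.ok = TRUE,
                          choices = c("found_in_either", "found_in_both",
                                      "global", "bonferroni",
                                      "prespecified_U", "prespecified_E"))
  need <- c("base", "E", "U")
  if ("global" %in% strategies) need <- c(need, "EU")
  base_spec <- eu_base_spec()

  out <- list()
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    seed_s <- eu_derive_seed(seed, si)
    rej <- stats::setNames(numeric(length(strategies)), strategies)
    n_valid <- 0L
    for (r in seq_len(reps)) {
      d <- eu_simulate(s, seed = eu_derive_seed(seed_s, r))
      fits <- suppressWarnings(
        eu_variable_fits(d, base_spec, "P", which = need))
      if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
        next
      }
      n_valid <- n_valid + 1L
      for (st in strategies) {
        res <- eu_test_variable(NULL, base_spec, "P", strategy = st,
                                alpha = alpha, fits = fits)
        if (isTRUE(res$significant)) rej[[st]] <- rej[[st]] + 1
      }
      if (verbose && r %% 200 == 0) {
        message(names(scenarios)[si], ": ", r, "/", reps, " replicates")
      }
    }
    prop <- if (n_valid > 0) rej / n_valid else rep(NA_real_, length(rej))
    out[[si]] <- cbind(scenario_row(names(scenarios)[si], s),
                       data.frame(metric = "rejection",
                                  strategy = strategies,
                                  proportion = unname(prop),
                                  mc_se = sqrt(unname(prop) *
                                                 (1 - unname(prop)) /
                                                 max(n_valid, 1)),
                                  n_valid = n_valid,
                                  n_dropped = reps - n_valid,
                                  row.names = NULL))
  }
  res <- do.call(rbind, out)
  class(res) <- c("eu_study_table", class(res))
  res
}

#' Sub-model classification study (E vs U placement)
#'
#' For scenarios with the effect of `P` in exactly one sub-model (or in
#' none), simulates `reps` datasets, selects the placement by information
#' criterion ([eu_select_submodel()]) and tallies the proportion of
#' replicates in which the true sub-model is chosen. In null scenarios the
#' E placement is taken as the reference "correct" label, so an unbiased
#' procedure scores 50%. Per-replicate absolute BIC differences and
#' outcomes are kept (attribute `"replicates"`) for evidence-calibration
#' binning with [eu_bin_calibration()]. Exact IC ties are recorded and
#' excluded from the correct/incorrect tally.
#'
#' @inheritParams eu_rejection_study
#' @return A data frame of class `eu_study_table` with one row per
#'   scenario (`metric = "correct_classification"`), with attribute
#'   `"replicates"`: a data frame with one row per valid replicate
#'   (`scenario_id`, `rep`, `truth`, `chosen`, `correct`, `delta_bic`,
#'   `tie`).
#' @export
eu_classification_study <- function(scenarios, reps = 1000, seed = 1,
                                    verbose = FALSE) {
  scenarios <- as_scenario_list(scenarios)
  base_spec <- eu_base_spec()
  out <- list()
  repl <- list()
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    if (s$beta_up != 0 && s$beta_ep2 != 0) {
      stop("scenario '", names(scenarios)[si], "' has effects in both ",
           "sub-models; classification truth is undefined", call. = FALSE)
    }
    truth <- if (s$beta_up != 0) "U" else "E"
    seed_s <- eu_derive_seed(seed, si)
    rows <- vector("list", reps)
    n_valid <- 0L
    for (r in seq_len(reps)) {
      d <- eu_simulate(s, seed = eu_derive_seed(seed_s, r))
      fits <- suppressWarnings(
        eu_variable_fits(d, base_spec, "P", which = c("E", "U")))
      sel <- eu_select_submodel(NULL, base_spec, "P", fits = fits)
      if (!sel$valid) next
      n_valid <- n_valid + 1L
      rows[[n_valid]] <- data.frame(
        scenario_id = names(scenarios)[si], rep = r, truth = truth,
        chosen = if (sel$tie) NA_character_ else sel$chosen_aic,
        correct = if (sel$tie) NA else sel$chosen_aic == truth,
        delta_bic = sel$delta, tie = sel$tie, stringsAsFactors = FALSE)
      if (verbose && r %% 200 == 0) {
        message(names(scenarios)[si], ": ", r, "/", reps, " replicates")
      }
    }
    rows <- do.call(rbind, rows[seq_len(n_valid)])
    repl[[si]] <- rows
    n_tied <- if (n_valid) sum(rows$tie) else 0L
    n_dec <- n_valid - n_tied
    prop <- if (n_dec > 0) sum(rows$correct, na.rm = TRUE) / n_dec else NA_real_
    out[[si]] <- cbind(scenario_row(names(scenarios)[si], s),
                       data.frame(metric = "correct_classification",
                                  strategy = "aic_bic",
                                  proportion = prop,
                                  mc_se = sqrt(prop * (1 - prop) /
                                                 max(n_dec, 1)),
                                  n_valid = n_valid,
                                  n_dropped = reps - n_valid,
                                  n_ties = n_tied,
                                  row.names = NULL))
  }
  res <- do.call(rbind, out)
  class(res) <- c("eu_study_table", class(res))
  attr(res, "replicates") <- do.call(rbind, repl)
  res
}

#' Calibration of BIC-difference evidence bands
#'
#' Pools the replicate-level results of a classification study, bins each
#' replicate by its absolute BIC difference into the evidence bands of
#' [eu_raftery_grade()] and reports the observed proportion of correct
#' sub-model assignments per band, for comparison with the expected
#' proportions.
#'
#' @param study result of [eu_classification_study()] (or its
#'   `"replicates"` attribute).
#' @return A data frame with one row per band: `bin`, `expected_lo`,
#'   `expected_hi`, `n`, `n_correct`, `proportion`, `mc_se`.
#' @export
eu_bin_calibration <- function(study) {
  repl <- if (is.data.frame(study) && !is.null(attr(study, "replicates"))) {
    attr(study, "replicates")
  } else {
    study
  }
  stopifnot(is.data.frame(repl), all(c("delta_bic", "correct") %in%
                                       names(repl)))
  repl <- repl[!is.na(repl$correct), , drop = FALSE]
  bins <- cut(repl$delta_bic, c(0, 2, 6, 10, Inf), right = FALSE,
              labels = c("[0,2)", "[2,6)", "[6,10)", "[10,Inf)"))
  n <- as.vector(table(bins))
  nc <- as.vector(tapply(repl$correct, bins, sum, default = 0))
  prop <- ifelse(n > 0, nc / n, NA_real_)
  data.frame(bin = levels(bins),
             expected_lo = c(0.50, 0.75, 0.95, 0.99),
             expected_hi = c(0.75, 0.95, 0.99, 1.00),
             n = n, n_correct = nc, proportion = prop,
             mc_se = ifelse(n > 0, sqrt(prop * (1 - prop) / pmax(n, 1)),
                            NA_real_))
}

#' Four-model selection study
#'
#' For each scenario, simulates `reps` datasets and selects among the four
#' inclusion models for `P` (omit, in E, in U, in both) by the requested
#' criterion, reporting the proportion of replicates assigned to each model
#' (plus exact ties, reported separately; the proportions and the tie rate
#' sum to 1).
#'
#' @inheritParams eu_rejection_study
#' @param criterion `"bic"` or `"aic"`.
#' @return A data frame of class `eu_study_table` with one row per
#'   scenario x model label (`strategy` in `null`, `E`, `U`, `EU`, `tie`).
#' @export
eu_four_model_study <- function(scenarios, reps = 1000,
                                criterion = c("bic", "aic"), seed = 1,
                                verbose = FALSE) {
  criterion <- match.arg(criterion)
  scenarios <- as_scenario_list(scenarios)
  base_spec <- eu_base_spec()
  labels <- c("null", "E", "U", "EU", "tie")
  out <- list()
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    seed_s <- eu_derive_seed(seed, si)
    counts <- stats::setNames(numeric(5), labels)
    n_valid <- 0L
    for (r in seq_len(reps)) {
      d <- eu_simulate(s, seed = eu_derive_seed(seed_s, r))
      fits <- suppressWarnings(eu_variable_fits(d, base_spec, "P"))
      sel <- eu_select_models(NULL, base_spec, "P", criterion = criterion,
                              fits = fits)
      if (!sel$valid) next
      n_valid <- n_valid + 1L
      lab <- if (sel$tie) "tie" else sel$chosen
      counts[[lab]] <- counts[[lab]] + 1
      if (verbose && r %% 200 == 0) {
        message(names(scenarios)[si], ": ", r, "/", reps, " replicates")
      }
    }
    prop <- if (n_valid > 0) counts / n_valid else rep(NA_real_, 5)
    out[[si]] <- cbind(scenario_row(names(scenarios)[si], s),
                       data.frame(metric = paste0("assigned_", criterion),
                                  strategy = labels,
                                  proportion = unname(prop),
                                  mc_se = sqrt(unname(prop) *
                                                 (1 - unname(prop)) /
                                                 max(n_valid, 1)),
                                  n_valid = n_valid,
                                  n_dropped = reps - n_valid,
                                  row.names = NULL))
  }
  res <- do.call(rbind, out)
  class(res) <- c("eu_study_table", class(res))
  res
}

#' Naive single-level logistic power estimate
#'
#' The power approximation an analyst would get from standard software by
#' treating one sub-model in isolation: a plain logistic model with a
#' standard-normal covariate with coefficient `effect`, the number of
#' cycles as sample size and the overall pregnancy rate as event rate. The
#' intercept is solved so that the marginal event rate matches
#' `event_rate`, the coefficient is tested with a 1-df likelihood-ratio
#' test, and the rejection proportion over `reps` simulations is returned.
#' Because success in an EU model additionally requires the other
#' component, this naive estimate badly over-states the power actually
#' available for either sub-model effect.
#'
#' @param effect logistic regression coefficient of the covariate.
#' @param n observations per simulated dataset.
#' @param event_rate marginal event probability.
#' @param reps number of simulated datasets.
#' @param alpha nominal significance level.
#' @param seed integer seed.
#' @return A data frame with `power`, `mc_se` and `reps`.
#' @export
eu_naive_logistic_power <- function(effect, n, event_rate, reps = 1000,
                                    alpha = 0.05, seed = 1) {
  stopifnot(event_rate > 0, event_rate < 1, n >= 2, reps >= 1)
  # intercept such that E[plogis(a + effect * Z)] = event_rate, Z ~ N(0,1)
  marg <- function(a) {
    stats::integrate(function(z) stats::plogis(a + effect * z) *
                       stats::dnorm(z),
                     -Inf, Inf)$value - event_rate
  }
  a <- stats::uniroot(marg, c(-20, 20), tol = 1e-10)$root
  rej <- 0L
  for (r in seq_len(reps)) {
    p <- with_seed(eu_derive_seed(seed, r), {
      x <- stats::rnorm(n)
      y <- stats::rbinom(n, 1L, stats::plogis(a + effect * x))
      f1 <- stats::glm(y ~ x, family = stats::binomial())
      stat <- f1$null.deviance - f1$deviance
      stats::pchisq(stat, 1, lower.tail = FALSE)
    })
    if (p < alpha) rej <- rej + 1L
  }
  power <- rej / reps
  data.frame(power = power, mc_se = sqrt(power * (1 - power) / reps),
             reps = reps)
}

#' Write a study table to CSV
#'
#' @param table an `eu_study_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_eu_study <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
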