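#' Grade the evidence carried by a BIC difference
#'
#' The BIC difference between two candidate models approximates twice the
#' log Bayes factor; Raftery's rule of thumb translates it into evidence
#' grades with an expected proportion of correct model choices. The bands
#' are half-open, `[0,2)` Weak, `[2,6)` Positive, `[6,10)` Strong and
#' `[10, Inf)` Very strong (printed band ends are assigned to the higher
#' grade).
#'
#' @param ic_difference non-negative IC difference (BIC, or equivalently
#'   AIC when the candidates have the same number of parameters).
#' @return An object of class `eu_evidence_grade`: list with `label`
#'   (`Weak`, `Positive`, `Strong`, `Very strong`), `bin` (the band as
#'   `c(lo, hi)`) and `expected_correct` (the expected proportion of
#'   correct assignments, as a `c(lo, hi)` interval on the 0-1 scale).
#' @export
#' @examples
#' eu_raftery_grade(3.5)   # Positive
#' eu_raftery_grade(12)    # Very strong
eu_raftery_grade <- function(ic_difference) {
  if (length(ic_difference) != 1L || !is.finite(ic_difference) ||
      ic_difference < 0) {
    stop("ic_difference must be a single non-negative number", call. = FALSE)
  }
  i <- findInterval(ic_difference, c(0, 2, 6, 10))
  labels <- c("Weak", "Positive", "Strong", "Very strong")
  bins <- list(c(0, 2), c(2, 6), c(6, 10), c(10, Inf))
  expected <- list(c(0.50, 0.75), c(0.75, 0.95), c(0.95, 0.99), c(0.99, 1))
  structure(list(label = labels[i], bin = bins[[i]],
                 expected_correct = expected[[i]]),
            class = "eu_evidence_grade")
}

#' @export
print.eu_evidence_grade <- function(x, ...) {
  cat(x$label, " evidence (IC difference in [", x$bin[1], ", ", x$bin[2],
      "); expected correct assignment ",
      100 * x$expected_correct[1], "-", 100 * x$expected_correct[2], "%)\n",
      sep = "")
  invisible(x)
}

#' Choose the sub-model of a patient-level variable by information criterion
#'
#' Fits the model with the variable in the embryo sub-model and the model
#' with it in the uterus sub-model, and selects the placement with the
#' smaller information criterion. The two candidates have the same number
#' of parameters, so AIC and BIC differ by a constant and give the same
#' choice and the same difference; the absolute difference is graded with
#' [eu_raftery_grade()].
#'
#' @inheritParams eu_test_variable
#' @param fits optional pre-computed list with elements `E` and `U`.
#' @return An object of class `eu_selection`: list with `candidates`
#'   (data frame of model, logLik, aic, bic), `chosen_aic`, `chosen_bic`,
#'   `delta` (absolute IC difference between the two placements), `grade`,
#'   `tie` and `valid`.
#' @export
eu_select_submodel <- function(data, base_spec, variable, fits = NULL) {
  if (is.null(fits)) {
    fits <- eu_variable_fits(data, base_spec, variable, which = c("E", "U"))
  }
  stopifnot(all(c("E", "U") %in% names(fits)))
  valid <- isTRUE(fits$E$converged) && isTRUE(fits$U$converged)
  cand <- data.frame(model = c("E", "U"),
                     logLik = c(fits$E$logLik, fits$U$logLik),
                     aic = c(fits$E$aic, fits$U$aic),
                     bic = c(fits$E$bic, fits$U$bic))
  delta <- abs(cand$aic[1] - cand$aic[2])
  tie <- valid && cand$aic[1] == cand$aic[2]
  chosen <- if (!valid || tie) NA_character_ else
    cand$model[which.min(cand$aic)]
  structure(list(candidates = cand,
                 chosen_aic = chosen, chosen_bic = chosen,
                 delta = if (valid) delta else NA_real_,
                 grade = if (valid) eu_raftery_grade(delta) else NULL,
                 tie = tie, valid = valid),
            class = "eu_selection")
}

#' Choose among the four inclusion models for a patient-level variable
#'
#' A variable being considered for inclusion can be omitted, placed in the
#' embryo sub-model, in the uterus sub-model, or in both. All four models
#' are fitted and the one minimising the requested criterion is chosen
#' (BIC uses the number of cycles as sample size).
#'
#' @inheritParams eu_test_variable
#' @param criterion `"bic"` or `"aic"`.
#' @param fits optional pre-computed list with elements `base`, `E`, `U`,
#'   `EU`.
#' @return An object of class `eu_selection4`: list with `candidates`
#'   (data frame of model, p, logLik, aic, bic), `criterion`, `chosen`
#'   (`"null"`, `"E"`, `"U"` or `"EU"`; `NA` on a tie), `tie` and `valid`.
#' @export
eu_select_models <- function(data, base_spec, variable,
                             criterion = c("bic", "aic"), fits = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(fits)) {
    fits <- eu_variable_fits(data, base_spec, variable)
  }
  stopifnot(all(c("base", "E", "U", "EU") %in% names(fits)))
  valid <- all(vapply(fits[c("base", "E", "U", "EU")],
                      function(f) isTRUE(f$converged), logical(1)))
  cand <- data.frame(model = c("null", "E", "U", "EU"),
                     p = vapply(fits[c("base", "E", "U", "EU")],
                                function(f) f$n_par, numeric(1)),
                     logLik = vapply(fits[c("base", "E", "U", "EU")],
                                     function(f) f$logLik, numeric(1)),
                     aic = vapply(fits[c("base", "E", "U", "EU")],
                                  function(f) f$aic, numeric(1)),
                     bic = vapply(fits[c("base", "E", "U", "EU")],
                                  function(f) f$bic, numeric(1)))
  rownames(cand) <- NULL
  ics <- cand[[criterion]]
  tie <- valid && sum(ics == min(ics)) > 1L
  chosen <- if (!valid || tie) NA_character_ else cand$model[which.min(ics)]
  structure(list(candidates = cand, criterion = criterion,
                 chosen = chosen, tie = tie, valid = valid),
            class = "eu_selection4")
}

#' @export
print.eu_selection <- function(x, ...) {
  cat("Sub-model selection (E vs U placement)\n")
  print(x$candidates, row.names = FALSE)
  if (!x$valid) {
    cat("INVALID: a fit did not converge\n")
  } else if (x$tie) {
    cat("exact IC tie\n")
  } else {
    cat("chosen: ", x$chosen_aic, " (|delta IC| = ",
        format(x$delta, digits = 4), ", ", x$grade$label, " evidence)\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.eu_selection4 <- function(x, ...) {
  cat("Four-model selection by ", toupper(x$criterion), "\n", sep = "")
  print(x$candidates, row.names = FALSE)
  if (!x$valid) {
    cat("INVALID: a fit did not converge\n")
  } else {
    cat("chosen:", if (x$tie) "(tie)" else x$chosen, "\n")
  }
  invisible(x)
}

#' Summarise a variable's placement: IC differences and tests
#'
#' The model-building workflow for one putative variable: fit the four
#' inclusion models (omit, in E, in U, in both), report each model's AIC
#' and BIC as differences from the null model, and the 1-df and 2-df
#' likelihood-ratio p-values. Negative IC differences favour including the
#' variable in that position.
#'
#' @inheritParams eu_select_models
#' @param alpha nominal significance level used when printing decisions.
#' @return An object of class `eu_variable_report`: list with `variable`,
#'   `table` (data frame: model, p, logLik, delta_aic, delta_bic, df,
#'   p_value), `alpha` and `valid`.
#' @export
eu_variable_report <- function(data, base_spec, variable, alpha = 0.05) {
  fits <- eu_variable_fits(data, base_spec, variable)
  valid <- all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  tab <- data.frame(model = c("null", "E", "U", "EU"),
                    p = vapply(fits[c("base", "E", "U", "EU")],
                               function(f) f$n_par, numeric(1)),
                    logLik = vapply(fits[c("base", "E", "U", "EU")],
                                    function(f) f$logLik, numeric(1)))
  tab$delta_aic <- vapply(fits[c("base", "E", "U", "EU")],
                          function(f) f$aic - fits$base$aic, numeric(1))
  tab$delta_bic <- vapply(fits[c("base", "E", "U", "EU")],
                          function(f) f$bic - fits$base$bic, numeric(1))
  tab$df <- c(NA, 1, 1, 2)
  tab$p_value <- NA_real_
  if (valid) {
    tab$p_value[2] <- eu_lrtest(fits$E, fits$base)$p_value
    tab$p_value[3] <- eu_lrtest(fits$U, fits$base)$p_value
    tab$p_value[4] <- eu_lrtest(fits$EU, fits$base)$p_value
  }
  rownames(tab) <- NULL
  structure(list(variable = variable, table = tab, alpha = alpha,
                 valid = valid),
            class = "eu_variable_report")
}

#' @export
print.eu_variable_report <- function(x, digits = 3, ...) {
  cat("Placement report for variable '", x$variable, "'\n", sep = "")
  tab <- x$table
  tab$logLik <- round(tab$logLik, digits)
  tab$delta_aic <- round(tab$delta_aic, digits)
  tab$delta_bic <- round(tab$delta_bic, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  if (x$valid) {
    pe <- x$table$p_value[2]; pu <- x$table$p_value[3]
    cat("Bonferroni decision at alpha = ", x$alpha, ": ",
        if (min(pe, pu) < x$alpha / 2) "significant" else "not significant",
        "\n", sep = "")
  } else {
    cat("INVALID: a fit did not converge\n")
  }
  invisible(x)
}
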