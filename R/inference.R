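#' Likelihood-ratio test between nested EU fits
#'
#' @param full `eu_fit` of the larger model.
#' @param reduced `eu_fit` of a model nested within `full` (its U and E
#'   terms must be subsets of the full model's).
#' @return An object of class `eu_lrtest`: list with `statistic`
#'   (clipped at 0), `df` and `p_value` (upper-tail chi-square).
#' @export
eu_lrtest <- function(full, reduced) {
  stopifnot(inherits(full, "eu_fit"), inherits(reduced, "eu_fit"))
  if (!full$converged || !reduced$converged) {
    stop("both fits must have converged for a likelihood-ratio test",
         call. = FALSE)
  }
  if (!all(reduced$spec$u_terms %in% full$spec$u_terms) ||
      !all(reduced$spec$e_terms %in% full$spec$e_terms)) {
    stop("the reduced model is not nested within the full model",
         call. = FALSE)
  }
  df <- full$n_par - reduced$n_par
  if (df < 1L) {
    stop("the full model must have more parameters than the reduced model",
         call. = FALSE)
  }
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "eu_lrtest")
}

#' @export
print.eu_lrtest <- function(x, ...) {
  cat("LR test: statistic = ", format(x$statistic, digits = 5),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# Fit the candidate models for a patient-level variable: the base model and
# the base with the variable added to the E, the U, or both sub-models.
eu_variable_fits <- function(data, base_spec, variable,
                             which = c("base", "E", "U", "EU"), ...) {
  stopifnot(inherits(data, "eu_data"), inherits(base_spec, "eu_spec"))
  if (!(variable %in% data$schema$cycle)) {
    stop("'", variable, "' is not a cycle-level covariate of the dataset",
         call. = FALSE)
  }
  if (variable %in% c(base_spec$u_terms, base_spec$e_terms)) {
    stop("'", variable, "' is already in the base model", call. = FALSE)
  }
  fits <- list()
  if ("base" %in% which) fits$base <- eu_fit(data, base_spec, ...)
  if ("E" %in% which) {
    fits$E <- eu_fit(data, eu_spec_add(base_spec, variable, "e"), ...)
  }
  if ("U" %in% which) {
    fits$U <- eu_fit(data, eu_spec_add(base_spec, variable, "u"), ...)
  }
  if ("EU" %in% which) {
    fits$EU <- eu_fit(data, eu_spec_add(base_spec, variable, "both"), ...)
  }
  fits
}

#' Test a patient-level variable whose sub-model is unknown
#'
#' A patient-level covariate can act through the uterus sub-model, the
#' embryo sub-model, or both, and the analyst usually does not know which.
#' This function implements the testing strategies for this situation.
#' Writing `p_E` and `p_U` for the 1-df likelihood-ratio p-values of the
#' variable added to the E and to the U sub-model, and `p_global` for the
#' 2-df test of the variable added to both:
#'
#' * `found_in_either` — significant if `min(p_E, p_U) < alpha`
#'   (anti-conservative: two tests at the nominal level);
#' * `found_in_both` — significant if `max(p_E, p_U) < alpha`
#'   (conservative);
#' * `bonferroni` — significant if `min(p_E, p_U) < alpha/2`;
#' * `global` — significant if the single 2-df `p_global < alpha`;
#' * `prespecified_E` / `prespecified_U` — the single 1-df test in the
#'   named sub-model at `alpha`, for when the sub-model can be fixed in
#'   advance.
#'
#' @param data an `eu_data` object.
#' @param base_spec `eu_spec` of the model without the variable.
#' @param variable name of a cycle-level covariate not in `base_spec`.
#' @param strategy one of the strategies above.
#' @param alpha nominal significance level.
#' @param fits optional pre-computed list of fits (elements `base`, `E`,
#'   `U`, `EU` as required by the strategy), e.g. from a replication
#'   engine that shares fits across strategies.
#' @return An object of class `eu_strategy_result`: list with `strategy`,
#'   `p_E`, `p_U`, `p_global` (NA when not computed by the strategy),
#'   `alpha`, `significant` and `valid` (`FALSE` if any required fit failed
#'   to converge, in which case `significant` is `NA`).
#' @export
eu_test_variable <- function(data, base_spec, variable,
                             strategy = c("bonferroni", "found_in_either",
                                          "found_in_both", "global",
                                          "prespecified_E", "prespecified_U"),
                             alpha = 0.05, fits = NULL) {
  strategy <- match.arg(strategy)
  need <- switch(strategy,
                 global = c("base", "EU"),
                 prespecified_E = c("base", "E"),
                 prespecified_U = c("base", "U"),
                 c("base", "E", "U"))
  if (is.null(fits)) {
    fits <- eu_variable_fits(data, base_spec, variable, which = need)
  }
  missing_fits <- setdiff(need, names(fits))
  if (length(missing_fits)) {
    stop("fits list is missing: ", paste(missing_fits, collapse = ", "),
         call. = FALSE)
  }
  valid <- all(vapply(fits[need], function(f) isTRUE(f$converged), logical(1)))

  p_E <- p_U <- p_global <- NA_real_
  significant <- NA
  if (valid) {
    if ("E" %in% need) p_E <- eu_lrtest(fits$E, fits$base)$p_value
    if ("U" %in% need) p_U <- eu_lrtest(fits$U, fits$base)$p_value
    if ("EU" %in% need) p_global <- eu_lrtest(fits$EU, fits$base)$p_value
    significant <- switch(strategy,
      found_in_either = min(p_E, p_U) < alpha,
      found_in_both   = max(p_E, p_U) < alpha,
      bonferroni      = min(p_E, p_U) < alpha / 2,
      global          = p_global < alpha,
      prespecified_E  = p_E < alpha,
      prespecified_U  = p_U < alpha)
  }
  structure(list(strategy = strategy, variable = variable,
                 p_E = p_E, p_U = p_U, p_global = p_global,
                 alpha = alpha, significant = significant, valid = valid),
            class = "eu_strategy_result")
}

#' @export
print.eu_strategy_result <- function(x, ...) {
  cat("Strategy '", x$strategy, "' for variable '", x$variable,
      "' at alpha = ", x$alpha, "\n", sep = "")
  pv <- c(p_E = x$p_E, p_U = x$p_U, p_global = x$p_global)
  pv <- pv[!is.na(pv)]
  if (length(pv)) {
    cat(paste(names(pv), "=", format(pv, digits = 4), collapse = ", "), "\n")
  }
  if (!x$valid) {
    cat("INVALID: a required fit did not converge\n")
  } else {
    cat("significant:", x$significant, "\n")
  }
  invisible(x)
}
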