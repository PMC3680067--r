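# Construct an eu_fit shell with prescribed log-likelihood, for exercising
# decision rules whose inputs are fitted models.
fake_fit <- function(spec, logLik, n_cycles = 100, converged = TRUE) {
  ic <- eu_information_criteria(logLik, spec$n_par, n_cycles)
  structure(list(spec = spec, logLik = logLik,
                 aic = ic[["aic"]], bic = ic[["bic"]],
                 n_par = spec$n_par, n_cycles = n_cycles,
                 converged = converged),
            class = "eu_fit")
}

# Fits whose 1-df LR p-values against `base` equal p_E/p_U and whose 2-df
# p-value equals p_global.
fake_strategy_fits <- function(p_E, p_U, p_global = NULL, ll0 = -500) {
  b <- eu_spec(u = "U", e = c("Ep", "Ee"))
  fits <- list(base = fake_fit(b, ll0),
               E = fake_fit(eu_spec_add(b, "P", "e"),
                            ll0 + qchisq(1 - p_E, 1) / 2),
               U = fake_fit(eu_spec_add(b, "P", "u"),
                            ll0 + qchisq(1 - p_U, 1) / 2))
  if (!is.null(p_global)) {
    fits$EU <- fake_fit(eu_spec_add(b, "P", "both"),
                        ll0 + qchisq(1 - p_global, 2) / 2)
  }
  fits
}
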