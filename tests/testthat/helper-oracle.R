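# Independent brute-force oracles: enumerate every joint (uterus state,
# viability vector) outcome explicitly. Deliberately kept free of the
# package's probability code paths.

oracle_kfold <- function(u, e, k) {
  n <- length(e)
  states <- expand.grid(c(rep(list(0:1), n), list(0:1)))  # v_1..v_n, uterus
  total <- 0
  for (r in seq_len(nrow(states))) {
    v <- as.numeric(states[r, seq_len(n)])
    w <- states[r, n + 1]
    k_out <- w * sum(v)
    if (k_out != k) next
    p <- if (w == 1) u else (1 - u)
    for (j in seq_len(n)) p <- p * (if (v[j] == 1) e[j] else 1 - e[j])
    total <- total + p
  }
  total
}

# Log-likelihood by direct enumeration, computing linear predictors by hand
# from the raw tables.
oracle_loglik <- function(data, spec, theta) {
  cyc <- data$cycles
  emb <- data$embryos
  total <- 0
  theta <- list(beta_u = unname(theta$beta_u), beta_e = unname(theta$beta_e))
  for (i in seq_len(nrow(cyc))) {
    eta_u <- theta$beta_u[1]
    for (t in seq_along(spec$u_terms)) {
      eta_u <- eta_u + theta$beta_u[t + 1] * cyc[[spec$u_terms[t]]][i]
    }
    u <- 1 / (1 + exp(-eta_u))
    rows <- which(emb$cycle_id == cyc$cycle_id[i])
    rows <- rows[order(emb$embryo_index[rows])]
    e <- numeric(length(rows))
    for (j in seq_along(rows)) {
      eta_e <- theta$beta_e[1]
      for (t in seq_along(spec$e_terms)) {
        v <- spec$e_terms[t]
        val <- if (v %in% names(emb)) emb[[v]][rows[j]] else cyc[[v]][i]
        eta_e <- eta_e + theta$beta_e[t + 1] * val
      }
      e[j] <- 1 / (1 + exp(-eta_e))
    }
    total <- total + log(oracle_kfold(u, e, cyc$k_observed[i]))
  }
  total
}

# Small deterministic toy datasets used across test files.
toy_det_cycle <- function(k = 0) {
  eu_dataset(data.frame(cycle_id = 1, n_transferred = 2, k_observed = k))
}

base_spec <- function() eu_spec(u = "U", e = c("Ep", "Ee"))
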