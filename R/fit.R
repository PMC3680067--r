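#' Maximum-likelihood fit of an EU model
#'
#' Maximises the EU log-likelihood by quasi-Newton (BFGS) iteration on the
#' unconstrained coefficient scale, followed by Newton polishing steps using
#' the observed information, so that the reported optimum has gradient norm
#' below `gtol`. The fit is deterministic given `data` and `spec`.
#'
#' Starting values are obtained by crude moment matching: the U intercept
#' from the overall success rate inflated by a factor 2 (success requires a
#' receptive uterus, so the success rate understates `u`), the E intercept
#' from the per-embryo implantation rate among successful cycles, and all
#' slopes at zero.
#'
#' With single-embryo transfers only, the two sub-models are identified only
#' through their product, so the observed information is singular along a
#' ridge; the sub-model split is identified through the twin rate when
#' multiple embryos are transferred. A condition number of the observed
#' information above `cond_warn` triggers an identifiability warning (the
#' fit is still returned: such data are statistically, not programmatically,
#' degenerate).
#'
#' @param data an `eu_data` object.
#' @param spec an `eu_spec`.
#' @param start optional `eu_params` with starting values.
#' @param gtol convergence tolerance on the Euclidean norm of the
#'   log-likelihood gradient.
#' @param maxit maximum BFGS iterations.
#' @param cond_warn condition-number threshold for the identifiability
#'   warning.
#' @param hessian compute the observed information (needed for `se` and
#'   `hessian_condition`; a few extra gradient evaluations).
#' @return An object of class `eu_fit` with components `spec`, `theta`
#'   (`eu_params` at the optimum), `coefficients` (flat named vector),
#'   `logLik`, `aic`, `bic`, `n_cycles`, `n_par`, `converged`,
#'   `gradient_norm`, `hessian_condition`, `se` (diagnostic standard errors
#'   from the inverse observed information, `NA` if not computable) and
#'   `n_bad_cycles`.
#' @export
#' @examples
#' cfg <- eu_scenario(n_cycles = 300, seed = 7)
#' d <- eu_simulate(cfg)
#' fit <- eu_fit(d, eu_spec(u = "U", e = c("Ep", "Ee")))
#' fit
eu_fit <- function(data, spec, start = NULL, gtol = 1e-8, maxit = 500L,
                   cond_warn = 1e8, hessian = TRUE) {
  fr <- eu_model_frame(data, spec)
  n <- length(fr$kobs)
  p <- fr$p_u + fr$p_e
  if (n < p) {
    warning("fewer cycles (", n, ") than free parameters (", p, ")",
            call. = FALSE)
  }

  if (is.null(start)) {
    par0 <- eu_start_values(fr)
  } else {
    check_theta(start, fr)
    par0 <- c(start$beta_u, start$beta_e)
  }

  # negative log-likelihood and gradient, cached per parameter value
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!identical(par, cache$par)) {
      sp <- eu_split_par(par, fr)
      r <- eu_loglik_cpp(sp$beta_u, sp$beta_e, fr$U, fr$E,
                         fr$estart, fr$ntrans, fr$kobs, TRUE)
      cache$par <- par
      cache$ll <- r$logL
      cache$gr <- c(r$grad_u, r$grad_e)
      cache$nbad <- length(r$bad_cycles)
    }
  }
  nll <- function(par) { eval_at(par); -cache$ll }
  ngr <- function(par) { eval_at(par); -cache$gr }

  opt <- stats::optim(par0, nll, ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  par <- opt$par

  # Newton polish on the observed information to drive the gradient to gtol;
  # near the optimum the likelihood change is below rounding noise, so steps
  # are accepted on gradient-norm descent rather than likelihood increase
  grad_at <- function(par) -ngr(par)
  g <- grad_at(par)
  H <- NULL
  for (it in seq_len(25L)) {
    gn <- sqrt(sum(g^2))
    if (gn <= gtol) break
    H <- num_jacobian(grad_at, par)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      step <- tryCatch(solve(H - 1e-8 * diag(p), g), error = function(e) NULL)
      if (is.null(step)) break
    }
    accepted <- FALSE
    lam <- 1
    while (lam > 1e-4) {
      par_new <- par - lam * step
      g_new <- grad_at(par_new)
      if (all(is.finite(g_new)) && sqrt(sum(g_new^2)) < gn) {
        par <- par_new
        g <- g_new
        accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted) break
  }

  ll <- -nll(par)
  gnorm <- sqrt(sum(grad_at(par)^2))
  converged <- is.finite(ll) && gnorm <= gtol
  n_bad <- cache$nbad

  se <- rep(NA_real_, p)
  cond <- NA_real_
  if (hessian) {
    if (is.null(H)) {
      H <- num_jacobian(grad_at, par)
      H <- (H + t(H)) / 2
    }
    info <- -H  # observed information
    sv <- svd(info, nu = 0, nv = 0)$d
    cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
    if (cond > cond_warn) {
      warning("observed information is near-singular (condition number ",
              format(cond, digits = 3), "); the U/E split may not be ",
              "identified (e.g. single-embryo transfers only)",
              call. = FALSE)
    }
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vc)) {
      dv <- diag(vc)
      se <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }

  sp <- eu_split_par(par, fr)
  theta <- eu_params(sp$beta_u, sp$beta_e, spec = spec)
  coefs <- c(sp$beta_u, sp$beta_e)
  names(coefs) <- c(paste0("U:", colnames(fr$U)), paste0("E:", colnames(fr$E)))
  names(se) <- names(coefs)
  ic <- eu_information_criteria(ll, p, n)

  structure(list(spec = spec, theta = theta, coefficients = coefs,
                 logLik = ll, aic = ic[["aic"]], bic = ic[["bic"]],
                 n_cycles = n, n_par = p, converged = converged,
                 gradient_norm = gnorm, hessian_condition = cond,
                 se = se, n_bad_cycles = n_bad,
                 counts = opt$counts),
            class = "eu_fit")
}

# Moment-matching starting values on the probability scale.
eu_start_values <- function(fr) {
  succ <- fr$kobs >= 1L
  p_succ <- mean(succ)
  u0 <- min(max(2 * p_succ, 0.02), 0.95)
  e0 <- if (any(succ)) {
    sum(fr$kobs[succ]) / sum(fr$ntrans[succ])
  } else {
    0.05
  }
  e0 <- min(max(e0, 0.02), 0.95)
  c(stats::qlogis(u0), numeric(fr$p_u - 1L),
    stats::qlogis(e0), numeric(fr$p_e - 1L))
}

# Central-difference Jacobian of a gradient function (observed Hessian).
num_jacobian <- function(fn, x, rel_h = 1e-6) {
  p <- length(x)
  J <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    h <- rel_h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 logL + 2p` and `BIC = -2 logL + p log(n)`. For EU models the
#' outcome is observed at the cycle (patient) level, so the BIC sample size
#' is the number of cycles, not the number of embryos.
#'
#' @param logL maximised log-likelihood.
#' @param p number of free parameters.
#' @param n_cycles number of cycles in the dataset.
#' @return Named numeric vector with elements `aic` and `bic`.
#' @export
#' @examples
#' eu_information_criteria(-100, 5, 100)
eu_information_criteria <- function(logL, p, n_cycles) {
  stopifnot(is.numeric(logL), length(logL) == 1L,
            p >= 1L, n_cycles >= 1L)
  c(aic = -2 * logL + 2 * p, bic = -2 * logL + p * log(n_cycles))
}

#' @export
print.eu_fit <- function(x, digits = 4, ...) {
  cat("<eu_fit> EU model, ", x$n_cycles, " cycles, ", x$n_par,
      " parameters\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, digits))
  cat("logLik ", format(x$logLik, digits = digits + 3),
      "  AIC ", format(x$aic, digits = digits + 3),
      "  BIC ", format(x$bic, digits = digits + 3), "\n", sep = "")
  cat("converged: ", x$converged,
      " (|grad| = ", format(x$gradient_norm, digits = 3),
      ", cond(info) = ", format(x$hessian_condition, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' @export
logLik.eu_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = object$n_cycles,
            class = "logLik")
}

#' @export
coef.eu_fit <- function(object, ...) object$coefficients
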