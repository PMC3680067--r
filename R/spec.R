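#' Specify an embryo-uterus model
#'
#' An EU model has two logistic sub-models: the uterus (U) sub-model for the
#' probability that the uterine environment is receptive, and the embryo (E)
#' sub-model for the per-embryo viability probability. Both sub-models always
#' contain an intercept; `u` and `e` name the additional covariates.
#' U-sub-model covariates must be cycle-level; E-sub-model covariates may be
#' embryo-level or cycle-level (a patient-level factor can act through
#' embryo viability, e.g. maternal age acting on egg quality).
#'
#' @param u character vector of cycle-level covariate names for the uterus
#'   sub-model (intercept implicit).
#' @param e character vector of covariate names for the embryo sub-model
#'   (intercept implicit).
#' @return An object of class `eu_spec` with elements `u_terms`, `e_terms`
#'   and `n_par` (total parameter count, intercepts included).
#' @export
#' @examples
#' eu_spec(u = "U", e = c("Ep", "Ee"))
eu_spec <- function(u = character(0), e = character(0)) {
  u <- as.character(u); e <- as.character(e)
  if (anyDuplicated(u) || anyDuplicated(e)) {
    stop("duplicated covariate name within a sub-model", call. = FALSE)
  }
  structure(list(u_terms = u, e_terms = e,
                 n_par = 2L + length(u) + length(e)),
            class = "eu_spec")
}

#' @export
print.eu_spec <- function(x, ...) {
  cat("<eu_spec> logit(u) ~ 1",
      if (length(x$u_terms)) paste0(" + ", paste(x$u_terms, collapse = " + ")),
      "\n          logit(e) ~ 1",
      if (length(x$e_terms)) paste0(" + ", paste(x$e_terms, collapse = " + ")),
      "\n          parameters: ", x$n_par, "\n", sep = "")
  invisible(x)
}

#' Add a covariate to one or both sub-models
#'
#' @param spec an `eu_spec`.
#' @param variable covariate name to add.
#' @param where `"e"`, `"u"` or `"both"`.
#' @return A new `eu_spec`.
#' @export
eu_spec_add <- function(spec, variable, where = c("e", "u", "both")) {
  stopifnot(inherits(spec, "eu_spec"))
  where <- match.arg(where)
  u <- spec$u_terms; e <- spec$e_terms
  if (where %in% c("u", "both")) {
    if (variable %in% u) stop("'", variable, "' already in the U sub-model",
                              call. = FALSE)
    u <- c(u, variable)
  }
  if (where %in% c("e", "both")) {
    if (variable %in% e) stop("'", variable, "' already in the E sub-model",
                              call. = FALSE)
    e <- c(e, variable)
  }
  eu_spec(u = u, e = e)
}

#' Parameter vector for an EU model
#'
#' @param beta_u numeric coefficients of the uterus sub-model, intercept
#'   first, aligned with `c("(Intercept)", spec$u_terms)`.
#' @param beta_e numeric coefficients of the embryo sub-model, intercept
#'   first.
#' @param spec optional `eu_spec` to validate lengths against.
#' @return An object of class `eu_params`.
#' @export
#' @examples
#' eu_params(beta_u = 0.1, beta_e = c(-3.66, 1, 1),
#'           spec = eu_spec(e = c("Ep", "Ee")))
eu_params <- function(beta_u, beta_e, spec = NULL) {
  beta_u <- as.numeric(beta_u); beta_e <- as.numeric(beta_e)
  if (!all(is.finite(beta_u)) || !all(is.finite(beta_e))) {
    stop("all coefficients must be finite", call. = FALSE)
  }
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "eu_spec"))
    if (length(beta_u) != length(spec$u_terms) + 1L) {
      stop("beta_u has length ", length(beta_u), " but the spec needs ",
           length(spec$u_terms) + 1L, " (intercept + u_terms)", call. = FALSE)
    }
    if (length(beta_e) != length(spec$e_terms) + 1L) {
      stop("beta_e has length ", length(beta_e), " but the spec needs ",
           length(spec$e_terms) + 1L, " (intercept + e_terms)", call. = FALSE)
    }
    names(beta_u) <- c("(Intercept)", spec$u_terms)
    names(beta_e) <- c("(Intercept)", spec$e_terms)
  }
  structure(list(beta_u = beta_u, beta_e = beta_e), class = "eu_params")
}

# Build aligned design matrices for the likelihood kernel.
#
# Returns intercept-first design matrices for both sub-models, with embryo
# rows grouped by cycle in cycle order. Cycle-level covariates named in the
# E sub-model are expanded to one row per embryo.
eu_model_frame <- function(data, spec) {
  stopifnot(inherits(data, "eu_data"), inherits(spec, "eu_spec"))
  cyc <- data$cycles
  n <- nrow(cyc)
  if (n == 0L) stop("dataset has no cycles", call. = FALSE)
  n_tr <- as.integer(cyc$n_transferred)

  bad_u <- setdiff(spec$u_terms, data$schema$cycle)
  if (length(bad_u)) {
    stop("U sub-model covariate(s) not found at cycle level: ",
         paste(bad_u, collapse = ", "), call. = FALSE)
  }
  bad_e <- setdiff(spec$e_terms, c(data$schema$cycle, data$schema$embryo))
  if (length(bad_e)) {
    stop("E sub-model covariate(s) not found in dataset: ",
         paste(bad_e, collapse = ", "), call. = FALSE)
  }

  U <- cbind(`(Intercept)` = rep(1, n))
  for (v in spec$u_terms) {
    col <- cyc[[v]]
    if (anyNA(col)) {
      stop("missing value for covariate '", v, "' in cycle ",
           cyc$cycle_id[which(is.na(col))[1]], call. = FALSE)
    }
    U <- cbind(U, col)
  }
  colnames(U) <- c("(Intercept)", spec$u_terms)

  n_emb <- sum(n_tr)
  E <- cbind(`(Intercept)` = rep(1, n_emb))
  for (v in spec$e_terms) {
    if (v %in% data$schema$embryo) {
      col <- data$embryos[[v]]   # already sorted to cycle order
      if (anyNA(col)) {
        stop("missing value for covariate '", v, "' in cycle ",
             data$embryos$cycle_id[which(is.na(col))[1]], call. = FALSE)
      }
    } else {
      col0 <- cyc[[v]]
      if (anyNA(col0)) {
        stop("missing value for covariate '", v, "' in cycle ",
             cyc$cycle_id[which(is.na(col0))[1]], call. = FALSE)
      }
      col <- rep(col0, times = n_tr)
    }
    E <- cbind(E, col)
  }
  colnames(E) <- c("(Intercept)", spec$e_terms)

  list(U = U, E = E,
       estart = c(0L, cumsum(n_tr)[-n]),
       ntrans = n_tr,
       kobs = as.integer(cyc$k_observed),
       cycle_id = cyc$cycle_id,
       p_u = ncol(U), p_e = ncol(E))
}

# Split a flat parameter vector into (beta_u, beta_e) for a frame.
eu_split_par <- function(par, frame) {
  list(beta_u = par[seq_len(frame$p_u)],
       beta_e = par[frame$p_u + seq_len(frame$p_e)])
}
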