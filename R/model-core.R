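#' Sub-model probabilities for each cycle
#'
#' Evaluates the two logistic sub-models: the uterine receptivity
#' probability `u_i` for each cycle and the viability probability `e_ij`
#' for each transferred embryo,
#' \deqn{\mathrm{logit}\, u_i = \beta_U' U_i, \qquad
#'       \mathrm{logit}\, e_{ij} = \beta_E' E_{ij}.}
#'
#' @param data an `eu_data` object.
#' @param spec an `eu_spec`.
#' @param theta an `eu_params` with coefficients aligned to `spec`.
#' @return A list with `u` (numeric vector, one receptivity probability per
#'   cycle, named by `cycle_id`) and `e` (list of numeric vectors, the
#'   viability probabilities of each cycle's embryos).
#' @export
eu_cycle_probabilities <- function(data, spec, theta) {
  fr <- eu_model_frame(data, spec)
  check_theta(theta, fr)
  u <- plogis(drop(fr$U %*% theta$beta_u))
  names(u) <- as.character(fr$cycle_id)
  e_all <- plogis(drop(fr$E %*% theta$beta_e))
  e <- split(e_all, rep(seq_along(fr$ntrans), times = fr$ntrans))
  names(e) <- as.character(fr$cycle_id)
  list(u = u, e = e)
}

check_theta <- function(theta, frame) {
  if (!inherits(theta, "eu_params")) {
    stop("theta must be an eu_params object", call. = FALSE)
  }
  if (length(theta$beta_u) != frame$p_u || length(theta$beta_e) != frame$p_e) {
    stop("parameter vector does not match the model spec (need ",
         frame$p_u, " U and ", frame$p_e, " E coefficients)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Probability of a k-fold pregnancy
#'
#' For a cycle with uterine receptivity probability `u` and embryo viability
#' probabilities `e = (e_1, ..., e_n)`, the probability of observing exactly
#' `k` implantations is
#' \deqn{P_k = (1-u)\,\delta(k) + u \sum_{|s|=k} \prod_j e_j^{s_j}
#'       (1-e_j)^{1-s_j},}
#' where \eqn{\delta(k)=1} if \eqn{k=0} and the sum runs over all subsets of
#' size `k` of the transferred embryos: an unreceptive uterus yields
#' \eqn{k=0} regardless of the embryos, otherwise the implantation count is
#' the number of viable embryos.
#'
#' The subset sum is enumerated exactly for up to `cap` embryos (transfer
#' numbers are small in practice); beyond the cap an equivalent
#' dynamic-programming convolution over embryos (the Poisson-binomial pmf)
#' is used.
#'
#' @param u uterine receptivity probability in `[0, 1]`.
#' @param e numeric vector of embryo viability probabilities in `[0, 1]`.
#' @param k integer implantation count, `0 <= k <= length(e)`.
#' @param cap maximum number of embryos for explicit subset enumeration.
#' @return The probability `P_k`.
#' @export
#' @examples
#' eu_kfold_probability(0.5, c(0.5), 0)       # 0.75
#' eu_kfold_probability(0.4, c(0.3, 0.2), 1)  # 0.152
eu_kfold_probability <- function(u, e, k, cap = 10L) {
  if (length(u) != 1L || !is.finite(u) || u < 0 || u > 1) {
    stop("u must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!length(e) || any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    stop("e must be probabilities in [0, 1]", call. = FALSE)
  }
  n <- length(e)
  if (length(k) != 1L || k != round(k) || k < 0 || k > n) {
    stop("k must be an integer in [0, length(e)]", call. = FALSE)
  }
  k <- as.integer(k)
  if (n <= cap) {
    # explicit sum over all subsets of size k
    if (k == 0L) {
      s <- prod(1 - e)
    } else if (k == n) {
      s <- prod(e)
    } else {
      subsets <- utils::combn(n, k)
      s <- sum(apply(subsets, 2L, function(idx) {
        prod(e[idx]) * prod(1 - e[-idx])
      }))
    }
  } else {
    # DP convolution over embryos; same quantity, O(n^2)
    f <- c(1, numeric(n))
    for (j in seq_len(n)) {
      f[2:(j + 1)] <- f[2:(j + 1)] * (1 - e[j]) + f[1:j] * e[j]
      f[1] <- f[1] * (1 - e[j])
    }
    s <- f[k + 1L]
  }
  (1 - u) * (k == 0L) + u * s
}

#' Log-likelihood of an EU model
#'
#' Sums `log P_{i,k_i}` over cycles, where `P_{i,k}` is the k-fold pregnancy
#' probability of [eu_kfold_probability()] evaluated at each cycle's fitted
#' `u_i` and `e_ij`. A cycle whose probability underflows to zero under
#' `theta` is floored at the smallest positive double and reported via a
#' warning and the `bad_cycles` attribute (such a cycle is structurally
#' impossible under `theta`, e.g. a twin pregnancy when a viability
#' probability is numerically zero).
#'
#' @inheritParams eu_cycle_probabilities
#' @return The log-likelihood (numeric scalar). Attribute `bad_cycles`
#'   lists the `cycle_id`s (if any) whose probability was floored.
#' @export
eu_loglik <- function(data, spec, theta) {
  fr <- eu_model_frame(data, spec)
  check_theta(theta, fr)
  r <- eu_loglik_cpp(theta$beta_u, theta$beta_e, fr$U, fr$E,
                     fr$estart, fr$ntrans, fr$kobs, FALSE)
  ll <- r$logL
  if (length(r$bad_cycles)) {
    ids <- fr$cycle_id[r$bad_cycles]
    warning("zero-probability cycle(s) under theta, floored: cycle_id ",
            paste(utils::head(ids, 5), collapse = ", "),
            if (length(ids) > 5) ", ...", call. = FALSE)
    attr(ll, "bad_cycles") <- ids
  }
  ll
}
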