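#' Derive a reproducible sub-seed
#'
#' Deterministic seed derivation used by the study engine: two Lehmer
#' (Park-Miller) multiplicative steps on the \eqn{2^{31}-1} field, exact in
#' double arithmetic. Every (base, index) pair gets its own stable seed, so
#' each replication of a study is individually re-runnable and the results
#' do not depend on loop order.
#'
#' @param base integer base seed.
#' @param index non-negative integer stream index (e.g. replicate number).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' eu_derive_seed(1, 1:3)[1] == eu_derive_seed(1, 1)
eu_derive_seed <- function(base, index) {
  m <- 2147483647
  a <- 48271
  x <- (abs(as.numeric(base)) %% (m - 1)) + 1
  x <- (a * x) %% m
  x <- ((x + as.numeric(index)) %% (m - 1)) + 1
  x <- (a * x) %% m
  x <- (a * x) %% m
  as.integer(x)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
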