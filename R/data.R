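#' Assemble an embryo-uterus dataset
#'
#' Bundles a cycle-level table and an optional embryo-level table into a
#' validated dataset for EU modelling. Each treatment cycle contributes one
#' row of `cycles`; each transferred embryo contributes one row of `embryos`.
#' Only the count of implantations per cycle (`k_observed`) is recorded:
#' with more than one embryo transferred the fate of individual embryos is
#' not observed, which is the partial-observability problem the EU
#' likelihood addresses.
#'
#' @param cycles data frame with required columns `cycle_id` (unique),
#'   `n_transferred` (integer, >= 1) and `k_observed` (integer,
#'   0 <= k <= n_transferred). Any additional numeric columns are treated as
#'   cycle-level (patient-level) covariates.
#' @param embryos optional data frame with required columns `cycle_id` and
#'   `embryo_index` (1-based within cycle; every cycle must have rows
#'   1..n_transferred). Additional numeric columns are embryo-level
#'   covariates. May be `NULL` when no embryo-level covariates are used.
#'
#' @return An object of class `eu_data`: a list with elements `cycles`,
#'   `embryos` (possibly `NULL`) and `schema` (names of cycle-level and
#'   embryo-level covariates).
#' @export
#' @examples
#' cyc <- data.frame(cycle_id = 1:2, n_transferred = c(1, 2),
#'                   k_observed = c(0, 1), U = c(-0.2, 0.3))
#' emb <- data.frame(cycle_id = c(1, 2, 2), embryo_index = c(1, 1, 2),
#'                   Ee = c(2.8, 3.1, 2.9))
#' eu_dataset(cyc, emb)
eu_dataset <- function(cycles, embryos = NULL) {
  cycles <- as.data.frame(cycles)
  req <- c("cycle_id", "n_transferred", "k_observed")
  miss <- setdiff(req, names(cycles))
  if (length(miss)) {
    stop("cycles table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cycles$cycle_id)) {
    dup <- unique(cycles$cycle_id[duplicated(cycles$cycle_id)])
    stop("duplicate cycle_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  n_tr <- cycles$n_transferred
  k <- cycles$k_observed
  if (!is.numeric(n_tr) || any(n_tr < 1) || any(n_tr != round(n_tr))) {
    stop("n_transferred must be a positive integer for every cycle",
         call. = FALSE)
  }
  if (!is.numeric(k) || any(k != round(k)) || any(k < 0) || any(k > n_tr)) {
    bad <- cycles$cycle_id[which(!is.numeric(k) | k < 0 | k > n_tr)[1]]
    stop("k_observed must be an integer in [0, n_transferred]; first ",
         "offending cycle_id: ", bad, call. = FALSE)
  }
  cyc_cov <- setdiff(names(cycles), req)
  for (v in cyc_cov) {
    if (!is.numeric(cycles[[v]])) {
      stop("cycle covariate '", v, "' is not numeric", call. = FALSE)
    }
  }

  emb_cov <- character(0)
  if (!is.null(embryos)) {
    embryos <- as.data.frame(embryos)
    reqe <- c("cycle_id", "embryo_index")
    misse <- setdiff(reqe, names(embryos))
    if (length(misse)) {
      stop("embryos table is missing required column(s): ",
           paste(misse, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(unique(embryos$cycle_id), cycles$cycle_id)
    if (length(unknown)) {
      stop("embryo rows reference unknown cycle_id: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    # every cycle must have embryo_index exactly 1..n_transferred
    idx <- split(embryos$embryo_index, factor(embryos$cycle_id,
                                              levels = cycles$cycle_id))
    for (i in seq_len(nrow(cycles))) {
      want <- seq_len(n_tr[i])
      got <- sort(idx[[i]])
      if (length(got) != length(want) || any(got != want)) {
        stop("cycle ", cycles$cycle_id[i], ": embryo_index must be exactly 1..",
             n_tr[i], " (found: ",
             paste(got, collapse = ","), ")", call. = FALSE)
      }
    }
    emb_cov <- setdiff(names(embryos), reqe)
    for (v in emb_cov) {
      if (!is.numeric(embryos[[v]])) {
        stop("embryo covariate '", v, "' is not numeric", call. = FALSE)
      }
    }
    if (length(intersect(emb_cov, cyc_cov))) {
      stop("covariate name(s) used at both levels: ",
           paste(intersect(emb_cov, cyc_cov), collapse = ", "), call. = FALSE)
    }
    # store embryos sorted to cycle order for downstream alignment
    ord <- order(match(embryos$cycle_id, cycles$cycle_id),
                 embryos$embryo_index)
    embryos <- embryos[ord, , drop = FALSE]
    rownames(embryos) <- NULL
  }

  structure(list(cycles = cycles, embryos = embryos,
                 schema = list(cycle = cyc_cov, embryo = emb_cov)),
            class = "eu_data")
}

#' @export
print.eu_data <- function(x, ...) {
  cat("<eu_data> ", nrow(x$cycles), " cycles, ",
      sum(x$cycles$n_transferred), " embryos transferred\n", sep = "")
  cat("  implantations (k): ",
      paste(sprintf("k=%d: %d", sort(unique(x$cycles$k_observed)),
                    tabulate(x$cycles$k_observed + 1L,
                             max(x$cycles$k_observed) + 1L)[
                      sort(unique(x$cycles$k_observed)) + 1L]),
            collapse = ", "), "\n", sep = "")
  cat("  cycle covariates:  ",
      if (length(x$schema$cycle)) paste(x$schema$cycle, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  embryo covariates: ",
      if (length(x$schema$embryo)) paste(x$schema$embryo, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Read an embryo-uterus dataset from CSV files
#'
#' Reads the two-file long format: a cycles CSV (one row per treatment
#' cycle) and an optional embryos CSV (one row per transferred embryo).
#' All validation of [eu_dataset()] applies, with row-level error messages.
#'
#' @param cycles_path path to the cycles CSV (columns `cycle_id`,
#'   `n_transferred`, `k_observed`, plus numeric cycle-level covariates).
#' @param embryos_path optional path to the embryos CSV (columns `cycle_id`,
#'   `embryo_index`, plus numeric embryo-level covariates).
#' @return An `eu_data` object.
#' @seealso [write_eu_dataset()]
#' @export
read_eu_dataset <- function(cycles_path, embryos_path = NULL) {
  if (!file.exists(cycles_path)) {
    stop("cycles file not found: ", cycles_path, call. = FALSE)
  }
  cyc <- utils::read.csv(cycles_path)
  emb <- NULL
  if (!is.null(embryos_path)) {
    if (!file.exists(embryos_path)) {
      stop("embryos file not found: ", embryos_path, call. = FALSE)
    }
    emb <- utils::read.csv(embryos_path)
  }
  eu_dataset(cyc, emb)
}

#' Write an embryo-uterus dataset to CSV files
#'
#' @param data an `eu_data` object.
#' @param cycles_path output path for the cycles CSV.
#' @param embryos_path output path for the embryos CSV; ignored when the
#'   dataset has no embryo table.
#' @return Invisibly, the paths written.
#' @export
write_eu_dataset <- function(data, cycles_path, embryos_path = NULL) {
  stopifnot(inherits(data, "eu_data"))
  utils::write.csv(data$cycles, cycles_path, row.names = FALSE)
  paths <- cycles_path
  if (!is.null(data$embryos) && !is.null(embryos_path)) {
    utils::write.csv(data$embryos, embryos_path, row.names = FALSE)
    paths <- c(paths, embryos_path)
  }
  invisible(paths)
}
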