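# Reporting odds ratio disproportionality screening.

#' Two-by-two contingency table for a drug-event pair
#'
#' Partitions the analysis table by target-event status and exposure to one
#' drug: `a` event & exposed, `b` event & unexposed, `c` non-event &
#' exposed, `d` non-event & unexposed.
#'
#' @param at an `analysis_table`.
#' @param drug_name drug to tabulate.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
make_contingency <- function(at, drug_name) {
  stopifnot(inherits(at, "analysis_table"), length(drug_name) == 1L)
  exposed_ids <- at$exposures$case_id[at$exposures$drug_name == drug_name]
  ev <- at$cases$event
  ex <- at$cases$case_id %in% exposed_ids
  c(a = sum(ev & ex), b = sum(ev & !ex), c = sum(!ev & ex),
    d = sum(!ev & !ex))
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' ROR = (a d) / (b c); the CI is the Woolf (log-normal) interval
#' exp(ln ROR +- z sqrt(1/a + 1/b + 1/c + 1/d)). A signal is positive when
#' the lower CI bound exceeds 1. With any zero cell the estimate is
#' undefined (`defined = FALSE`, values `NA`) unless the Haldane-Anscombe
#' +0.5 correction is enabled, which then adds 0.5 to all four cells.
#'
#' @param table named or positional numeric vector `c(a, b, c, d)` of
#'   non-negative counts.
#' @param haldane apply the +0.5 correction when any cell is zero
#'   (default `FALSE`).
#' @param conf_level confidence level (default 0.95).
#' @return List of class `ror_result`: `table`, `ror`, `ci_low`, `ci_high`,
#'   `signal`, `defined`.
#' @export
ror <- function(table, haldane = FALSE, conf_level = 0.95) {
  stopifnot(length(table) == 4L, all(table >= 0))
  tab <- as.numeric(table)
  names(tab) <- c("a", "b", "c", "d")
  work <- tab
  defined <- all(tab > 0)
  if (!defined && haldane) {
    work <- tab + 0.5
    defined <- TRUE
  }
  if (!defined) {
    out <- list(table = tab, ror = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, signal = FALSE, defined = FALSE)
    class(out) <- "ror_result"
    return(out)
  }
  est <- (work[["a"]] * work[["d"]]) / (work[["b"]] * work[["c"]])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / work))
  ci <- exp(log(est) + c(-1, 1) * z * se)
  out <- list(table = tab, ror = est, ci_low = ci[1], ci_high = ci[2],
              signal = ci[1] > 1, defined = TRUE)
  class(out) <- "ror_result"
  out
}

#' @export
print.ror_result <- function(x, ...) {
  cat("<ror_result>\n")
  cat(sprintf("  table (a,b,c,d): %s\n",
              paste(format(x$table, big.mark = ","), collapse = ", ")))
  if (x$defined) {
    cat(sprintf("  ROR %.2f (95%% CI %.2f-%.2f)  signal: %s\n",
                x$ror, x$ci_low, x$ci_high, x$signal))
  } else {
    cat("  undefined (zero cell, no correction)\n")
  }
  invisible(x)
}

#' Screen a drug list by reporting odds ratio
#'
#' One [ror()] per drug against the target event, sorted by descending
#' event-exposed count `a`. No multiplicity adjustment is applied.
#'
#' @param at an `analysis_table`.
#' @param drugs character vector of drugs; defaults to the
#'   [drugs_of_interest()] list.
#' @param haldane,conf_level passed to [ror()].
#' @return Tibble `drug`, `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`,
#'   `signal`, `defined`.
#' @export
ror_screen <- function(at, drugs = NULL, haldane = FALSE,
                       conf_level = 0.95) {
  stopifnot(inherits(at, "analysis_table"))
  if (is.null(drugs)) drugs <- drugs_of_interest(at)$drug
  if (!length(drugs)) {
    return(tibble::tibble(
      drug = character(0), a = integer(0), b = integer(0), c = integer(0),
      d = integer(0), ror = numeric(0), ci_low = numeric(0),
      ci_high = numeric(0), signal = logical(0), defined = logical(0)))
  }
  rows <- lapply(drugs, function(d) {
    r <- ror(make_contingency(at, d), haldane = haldane,
             conf_level = conf_level)
    tibble::tibble(drug = d, a = as.integer(r$table[["a"]]),
                   b = as.integer(r$table[["b"]]),
                   c = as.integer(r$table[["c"]]),
                   d = as.integer(r$table[["d"]]),
                   ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
                   signal = r$signal, defined = r$defined)
  })
  out <- do.call(rbind, rows)
  out[order(-out$a, out$drug), ]
}
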