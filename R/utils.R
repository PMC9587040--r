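# Shared low-level helpers: band parsing, quantile rule, date handling.

# JADER-style band labels use a plain hyphen in the canonical schema, but
# real extracts (and journal typography) carry assorted unicode dashes.
.dash_class <- "[-‐‑‒–—―−]"

#' Parse 10-unit band labels
#'
#' Parses labels such as `"160-169"` (height, cm), `"50-59"` (weight, kg) or
#' decade age bands including `"<10"` into their integer bounds.
#'
#' @param x character vector of band labels.
#' @return A data frame with columns `lo` and `hi` (integer, `NA` where the
#'   label does not parse).
#' @keywords internal
parse_band <- function(x) {
  x <- as.character(x)
  lo <- rep(NA_integer_, length(x))
  hi <- rep(NA_integer_, length(x))
  xx <- trimws(x)
  lt <- grepl("^<\\s*\\d+$", xx)
  if (any(lt, na.rm = TRUE)) {
    v <- as.integer(sub("^<\\s*", "", xx[which(lt)]))
    lo[which(lt)] <- 0L
    hi[which(lt)] <- v - 1L
  }
  pat <- paste0("^(\\d+)\\s*", .dash_class, "\\s*(\\d+)$")
  rng <- grepl(pat, xx) & !is.na(xx)
  if (any(rng)) {
    lo[rng] <- as.integer(sub(pat, "\\1", xx[rng]))
    hi[rng] <- as.integer(sub(pat, "\\2", xx[rng]))
  }
  data.frame(lo = lo, hi = hi)
}

# Lower bound of a band label; NA when unparseable.
band_lower <- function(x) parse_band(x)$lo

# TRUE where the label parses to an ordered range of width 10 (e.g. 160-169,
# or "<10" which stands for 0-9).
band_is_valid10 <- function(x) {
  b <- parse_band(x)
  !is.na(b$lo) & !is.na(b$hi) & (b$hi - b$lo == 9L)
}

#' Quantiles under the configurable order-statistic rule
#'
#' The package-wide quantile convention is linear interpolation between order
#' statistics at positions `(n + 1) * p`, i.e. `stats::quantile()` type 6;
#' the type is exposed so users matching other software can switch rule.
#'
#' @param x numeric vector.
#' @param probs probabilities.
#' @param quantile_type integer passed to [stats::quantile()] (default 6).
#' @return numeric vector of quantiles (unnamed).
#' @export
srs_quantile <- function(x, probs, quantile_type = 6L) {
  stats::quantile(x, probs = probs, type = quantile_type, names = FALSE)
}

# Full 8-digit YYYYMMDD -> Date; anything else (partial YYYYMM, blank, junk)
# -> NA.  Invalid calendar dates also come back NA.
parse_date8 <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{8}$", x)
  if (any(ok)) out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# TRUE for 6-digit YYYYMM partial dates (retained but flagged; excluded from
# time-to-onset, which needs fully dated records).
is_partial_date <- function(x) {
  x <- as.character(x)
  !is.na(x) & grepl("^\\d{6}$", x)
}

format_date8 <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

# Fixed-precision rendering used by the report writer (byte-stable output).
fmt_fixed <- function(x, digits) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & is.finite(x)
  out[ok] <- sprintf(paste0("%.", digits, "f"), x[ok])
  out[!ok & !is.na(x)] <- as.character(x[!ok & !is.na(x)])
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
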