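# Cohort construction: exclusions, eBMI, classifications, the analysis
# table, the time-to-onset table, drugs of interest and outcome profile.

#' Intermediate value of a 10-unit band
#'
#' JADER records height in 10-cm and weight in 10-kg bands. The continuous
#' stand-in for a band `L`-`L+9` is its intermediate value `L + 5` (so
#' `"160-169"` maps to 165 cm and `"50-59"` to 55 kg), not the arithmetic
#' midpoint `L + 4.5`.
#'
#' @param band character vector of band labels (`"<10"` is treated as 0-9).
#' @return numeric vector of intermediate values.
#' @export
#' @examples
#' intermediate_value(c("160-169", "50-59"))
intermediate_value <- function(band) {
  b <- parse_band(band)
  bad <- is.na(b$lo) | is.na(b$hi) | (b$hi - b$lo != 9L)
  if (any(bad)) {
    stop(sprintf("unparseable 10-unit band label(s): %s",
                 paste(sQuote(utils::head(band[bad], 5)), collapse = ", ")),
         call. = FALSE)
  }
  b$lo + 5
}

#' Estimated BMI from banded height and weight
#'
#' eBMI = intermediate weight (kg) / \[intermediate height (m)\]^2, reported
#' to one decimal: `compute_ebmi("160-169", "50-59")` is 55 / 1.65^2 = 20.2
#' kg/m^2.
#'
#' @param height_band,weight_band character vectors of 10-cm / 10-kg band
#'   labels (recycled to a common length).
#' @param digits decimals retained in the reported value (default 1).
#' @return numeric vector of eBMI values in kg/m^2.
#' @export
#' @examples
#' compute_ebmi("160-169", "50-59")  # 20.2
compute_ebmi <- function(height_band, weight_band, digits = 1) {
  h <- intermediate_value(height_band) / 100
  w <- intermediate_value(weight_band)
  round(w / h^2, digits)
}

#' Boxplot outlier bounds for eBMI
#'
#' The eBMI outlier rule: values outside `Q1 - 1.5 * IQR` to
#' `Q3 + 1.5 * IQR` are excluded, with quartiles computed under the
#' configured quantile rule.
#'
#' @param values numeric vector (at least 4 values).
#' @param quantile_type quantile rule (see [srs_quantile()]).
#' @return numeric length-2 vector `c(low, high)`.
#' @export
ebmi_outlier_bounds <- function(values, quantile_type = 6L) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop("at least 4 values are required for boxplot outlier bounds",
         call. = FALSE)
  }
  q <- srs_quantile(values, c(0.25, 0.75), quantile_type)
  iqr <- q[2] - q[1]
  c(low = q[1] - 1.5 * iqr, high = q[2] + 1.5 * iqr)
}

#' eBMI class
#'
#' Underweight below 18.5 kg/m^2, normal in \[18.5, 25.0), obese at or above
#' 25.0 — half-open intervals, so 18.5 is normal and 25.0 is obese.
#'
#' @param ebmi numeric vector of eBMI values (kg/m^2).
#' @return character vector in `{"underweight", "normal", "obese"}`.
#' @export
classify_ebmi <- function(ebmi) {
  out <- rep(NA_character_, length(ebmi))
  out[!is.na(ebmi) & ebmi < 18.5] <- "underweight"
  out[!is.na(ebmi) & ebmi >= 18.5 & ebmi < 25.0] <- "normal"
  out[!is.na(ebmi) & ebmi >= 25.0] <- "obese"
  out
}

.age_bands <- c("<10", "10-19", "20-29", "30-39", "40-49", "50-59",
                "60-69", "70-79", "80-89", "90-99", "100-109")

#' Build the analysis table
#'
#' Applies the dataset-construction flow: cases with missing or unparseable
#' sex, age band, height band or weight band are excluded; eBMI is computed
#' from the intermediate band values; eBMI outliers are excluded by the
#' boxplot rule applied once to the pooled post-exclusion distribution; the
#' remaining cases form the analysis table with age stratification
#' (>= 60 vs < 60, from the band's lower bound), eBMI class and the
#' target-event flag (any REAC row carrying `target_pt_code`).
#'
#' @param data a `jader_data` object.
#' @param target_pt_code MedDRA preferred-term code of the target event
#'   (default `"10056979"`, microscopic colitis).
#' @param quantile_type quantile rule for the outlier bounds.
#' @return An object of class `analysis_table`: list with
#'   \describe{
#'     \item{cases}{tibble: `case_id`, `sex`, `age_band`, `age_ge60`,
#'       `ebmi`, `ebmi_class`, `event`, `outcome`.}
#'     \item{exposures}{tibble of distinct (`case_id`, `drug_name`) pairs
#'       restricted to analysis cases.}
#'     \item{event_drug_records}{per-record drug rows (with dates) for event
#'       cases, feeding [build_tto_table()].}
#'     \item{event_onsets}{target-event onset dates for event cases.}
#'     \item{flowchart}{named counts for each construction step.}
#'     \item{ebmi_bounds}{the frozen outlier bounds.}
#'   }
#' @export
build_analysis_table <- function(data, target_pt_code = "10056979",
                                 quantile_type = 6L) {
  stopifnot(inherits(data, "jader_data"))
  demo <- data$demo
  n_input <- nrow(demo)

  sex_ok <- demo$sex %in% c("male", "female")
  age_ok <- !is.na(band_lower(demo$age_band)) & demo$age_band %in% .age_bands
  hw_ok <- band_is_valid10(demo$height_band) & band_is_valid10(demo$weight_band)
  complete <- sex_ok & age_ok & hw_ok
  n_excluded_missing <- sum(!complete)
  demo <- demo[complete, , drop = FALSE]

  ebmi <- if (nrow(demo)) {
    compute_ebmi(demo$height_band, demo$weight_band)
  } else numeric(0)

  if (length(ebmi) >= 4L) {
    bounds <- ebmi_outlier_bounds(ebmi, quantile_type)
    keep <- ebmi >= bounds["low"] & ebmi <= bounds["high"]
  } else {
    bounds <- c(low = -Inf, high = Inf)
    keep <- rep(TRUE, length(ebmi))
  }
  n_excluded_outlier <- sum(!keep)
  demo <- demo[keep, , drop = FALSE]
  ebmi <- ebmi[keep]

  reac <- data$reac
  target <- reac[reac$pt_code == target_pt_code, , drop = FALSE]
  event <- demo$case_id %in% target$case_id

  # outcome of the target event: first target-PT row per case, file order
  first_target <- target[!duplicated(target$case_id), , drop = FALSE]
  outcome <- first_target$outcome[match(demo$case_id, first_target$case_id)]
  outcome[is.na(outcome)] <- ""

  cases <- tibble::tibble(
    case_id = demo$case_id,
    sex = demo$sex,
    age_band = demo$age_band,
    age_ge60 = band_lower(demo$age_band) >= 60,
    ebmi = ebmi,
    ebmi_class = classify_ebmi(ebmi),
    event = event,
    outcome = outcome
  )

  drug <- data$drug[data$drug$case_id %in% cases$case_id, , drop = FALSE]
  exposures <- unique(tibble::tibble(case_id = drug$case_id,
                                     drug_name = drug$drug_name))
  ev_ids <- cases$case_id[cases$event]
  event_drug_records <- drug[drug$case_id %in% ev_ids,
                             c("case_id", "drug_name", "start_date")]
  event_onsets <- target[target$case_id %in% ev_ids,
                         c("case_id", "onset_date")]

  structure(
    list(
      cases = cases,
      exposures = exposures,
      event_drug_records = tibble::as_tibble(event_drug_records),
      event_onsets = tibble::as_tibble(event_onsets),
      flowchart = c(
        n_input = n_input,
        n_excluded_missing = n_excluded_missing,
        n_complete = n_input - n_excluded_missing,
        n_excluded_outlier = n_excluded_outlier,
        n_analysis = nrow(cases),
        n_event = sum(event)
      ),
      ebmi_bounds = bounds,
      target_pt_code = target_pt_code,
      quantile_type = quantile_type
    ),
    class = "analysis_table"
  )
}

#' @export
print.analysis_table <- function(x, ...) {
  fc <- x$flowchart
  cat("<analysis_table>\n")
  cat(sprintf("  input reports: %d\n", fc[["n_input"]]))
  cat(sprintf("  excluded (missing demographics): %d\n",
              fc[["n_excluded_missing"]]))
  cat(sprintf("  excluded (eBMI outliers): %d  [bounds %.1f-%.1f]\n",
              fc[["n_excluded_outlier"]],
              x$ebmi_bounds[["low"]], x$ebmi_bounds[["high"]]))
  cat(sprintf("  analysis table: %d cases, %d target-event cases\n",
              fc[["n_analysis"]], fc[["n_event"]]))
  invisible(x)
}

#' Build the time-to-onset table
#'
#' For every event case and every fully dated drug record (8-digit start
#' date) paired with a fully dated target-event onset, the duration is
#' onset minus start in days. Per (case, drug) the shortest duration is
#' kept; negative durations are treated as data errors, dropped and
#' counted; same-day onsets (duration 0) map to 0.5 days so they remain in
#' the strictly positive Weibull domain.
#'
#' @param at an `analysis_table`.
#' @param drugs optional character vector restricting to these drugs.
#' @return Tibble of onset records (`case_id`, `drug_name`,
#'   `duration_days`, `start_date`, `onset_date`) with attributes
#'   `n_negative_dropped` and `n_tto` (distinct event cases represented).
#' @export
build_tto_table <- function(at, drugs = NULL) {
  stopifnot(inherits(at, "analysis_table"))
  dr <- at$event_drug_records
  on <- at$event_onsets
  if (!is.null(drugs)) dr <- dr[dr$drug_name %in% drugs, , drop = FALSE]

  dr <- dr[!is.na(parse_date8(dr$start_date)), , drop = FALSE]
  on <- on[!is.na(parse_date8(on$onset_date)), , drop = FALSE]

  empty <- tibble::tibble(case_id = character(0), drug_name = character(0),
                          duration_days = numeric(0),
                          start_date = character(0), onset_date = character(0))
  if (!nrow(dr) || !nrow(on)) {
    attr(empty, "n_negative_dropped") <- 0L
    attr(empty, "n_tto") <- 0L
    return(empty)
  }

  m <- merge(as.data.frame(dr), as.data.frame(on), by = "case_id")
  if (!nrow(m)) {
    attr(empty, "n_negative_dropped") <- 0L
    attr(empty, "n_tto") <- 0L
    return(empty)
  }
  dur <- as.numeric(parse_date8(m$onset_date) - parse_date8(m$start_date))
  neg <- dur < 0
  n_neg <- sum(neg)
  m <- m[!neg, , drop = FALSE]
  dur <- dur[!neg]
  dur[dur == 0] <- 0.5

  key <- paste(m$case_id, m$drug_name, sep = "\r")
  ord <- order(key, dur)
  m <- m[ord, , drop = FALSE]
  dur <- dur[ord]
  first <- !duplicated(key[ord])

  out <- tibble::tibble(
    case_id = m$case_id[first],
    drug_name = m$drug_name[first],
    duration_days = dur[first],
    start_date = m$start_date[first],
    onset_date = m$onset_date[first]
  )
  out <- out[order(out$drug_name, out$case_id), ]
  attr(out, "n_negative_dropped") <- n_neg
  attr(out, "n_tto") <- length(unique(out$case_id))
  out
}

#' Drugs of interest grouped by frequency of use
#'
#' Among target-event cases, drugs administered in at least `min_cases`
#' distinct cases (default 5) are the drugs of interest, binned into the
#' frequency strata `>100`, `20-100`, `10-19` and `5-9`.
#'
#' @param at an `analysis_table`.
#' @param min_cases inclusion threshold on distinct event cases (default 5).
#' @return Tibble `drug`, `n_cases`, `stratum`, sorted by descending count
#'   then drug name.
#' @export
drugs_of_interest <- function(at, min_cases = 5L) {
  stopifnot(inherits(at, "analysis_table"))
  ev_ids <- at$cases$case_id[at$cases$event]
  expo <- at$exposures[at$exposures$case_id %in% ev_ids, , drop = FALSE]
  if (!nrow(expo)) {
    return(tibble::tibble(drug = character(0), n_cases = integer(0),
                          stratum = character(0)))
  }
  tab <- table(expo$drug_name)
  n <- as.integer(tab)
  keep <- n >= min_cases
  drug <- names(tab)[keep]
  n <- n[keep]
  stratum <- ifelse(n > 100, ">100",
             ifelse(n >= 20, "20-100",
             ifelse(n >= 10, "10-19", "5-9")))
  out <- tibble::tibble(drug = drug, n_cases = n, stratum = stratum)
  out[order(-out$n_cases, out$drug), ]
}

#' Clinical outcome profile of the target-event cases
#'
#' Counts event cases in each of the six outcome categories (Uncertain,
#' Recovered, Improved, Unimproved, WithSequelae, Death); cases with a
#' missing outcome are reported separately.
#'
#' @param at an `analysis_table`.
#' @return Tibble `outcome`, `n` with one row per category plus a
#'   `missing` row.
#' @export
tabulate_outcomes <- function(at) {
  stopifnot(inherits(at, "analysis_table"))
  oc <- at$cases$outcome[at$cases$event]
  n <- vapply(.outcome_levels, function(l) sum(oc == l), integer(1))
  tibble::tibble(outcome = c(.outcome_levels, "missing"),
                 n = c(unname(n), sum(!nzchar(oc))))
}
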