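# Synthetic spontaneous-report generator with known ground truth.
#
# The generator mirrors the downstream models exactly: event odds are
# log-linear in sex, age class, eBMI class (computed from the *banded*
# height/weight, so generator and pipeline share the covariate definition)
# and drug exposures; onset latency for the causative drug follows a
# configured Weibull law.

.default_drug_catalog <- function() {
  tibble::tibble(
    drug_name = c(
      "lansoprazole", "aspirin", "magnesium oxide", "rabeprazole",
      "amlodipine", "furosemide", "loxoprofen", "nicorandil",
      "allopurinol", "candesartan", "rosuvastatin", "carvedilol",
      "etizolam", "olmesartan", "alendronic acid", "rebamipide",
      "bisoprolol", "clopidogrel", "diclofenac", "flunitrazepam",
      "vonoprazan", "atorvastatin"
    ),
    exposure_probability = c(
      0.091, 0.083, 0.105, 0.042,
      0.070, 0.050, 0.050, 0.017,
      0.030, 0.040, 0.040, 0.020,
      0.030, 0.030, 0.020, 0.050,
      0.020, 0.030, 0.022, 0.017,
      0.016, 0.030
    )
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic
#' spontaneous-report generator. Defaults describe the study conditions the
#' pipeline is validated under: a mostly elderly reporting population with
#' heavy height/weight missingness, two drugs with injected effects
#' (odds ratios 35 and 2) among 20 null co-reported drugs, covariate
#' effects for female sex, age >= 60 and eBMI class, and per-drug Weibull
#' onset latencies.
#'
#' @param n_cases number of reports to generate.
#' @param seed integer RNG seed.
#' @param sex_proportion_female probability a case is female.
#' @param age_band_weights named probabilities over the 11 decade bands
#'   (`<10` ... `100-109`); must sum to 1.
#' @param height_mean_cm,height_sd_cm,weight_mean_kg,weight_sd_kg named
#'   numeric (`male`, `female`): latent continuous height/weight moments.
#' @param missing_rate named probabilities (`sex`, `age`, `height`,
#'   `weight`) of blanking each demographic field.
#' @param drug_catalog tibble/data.frame `drug_name`,
#'   `exposure_probability` (independent exposures).
#' @param target_pt_code preferred-term code of the target event.
#' @param baseline_event_logodds intercept of the event model.
#' @param covariate_effects named log-odds terms `female`, `age_ge60`,
#'   `obese`, `underweight`.
#' @param drug_effects named log odds ratios; names must appear in the
#'   catalog. Drugs absent from this list are null.
#' @param onset_models named list `drug -> c(alpha, beta)` Weibull scale
#'   (days) and shape for the causative-drug latency; every name must
#'   appear in the catalog.
#' @param background_onset `c(alpha, beta)` latency used when the event
#'   fires with no exposed effect drug.
#' @param date_window character length-2 `c(first, last)` as `YYYYMMDD`;
#'   drug start dates are uniform in this window.
#' @param start_date_missing_rate,onset_date_missing_rate probability a
#'   start/onset date is degraded (half to a 6-digit partial `YYYYMM`,
#'   half to blank), emulating the incomplete dating of real reports.
#' @param outcome_weights named probabilities over the six outcome
#'   categories; must sum to 1.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_cases = 20000L,
    seed = 1L,
    sex_proportion_female = 0.46,
    age_band_weights = c(
      "<10" = 0.02, "10-19" = 0.02, "20-29" = 0.04, "30-39" = 0.06,
      "40-49" = 0.08, "50-59" = 0.12, "60-69" = 0.20, "70-79" = 0.25,
      "80-89" = 0.15, "90-99" = 0.05, "100-109" = 0.01),
    height_mean_cm = c(male = 165, female = 152),
    height_sd_cm = c(male = 8, female = 7),
    weight_mean_kg = c(male = 62, female = 50),
    weight_sd_kg = c(male = 11, female = 9),
    missing_rate = c(sex = 0.01, age = 0.05, height = 0.40, weight = 0.40),
    drug_catalog = .default_drug_catalog(),
    target_pt_code = "10056979",
    baseline_event_logodds = stats::qlogis(0.01),
    covariate_effects = c(female = log(3.26), age_ge60 = log(3.94),
                          obese = log(1.21), underweight = log(1.17)),
    drug_effects = c(lansoprazole = log(35), aspirin = log(2)),
    onset_models = list(lansoprazole = c(alpha = 107, beta = 0.93),
                        aspirin = c(alpha = 221, beta = 0.57)),
    background_onset = c(alpha = 90, beta = 1),
    date_window = c("20040401", "20210831"),
    start_date_missing_rate = 0.3,
    onset_date_missing_rate = 0.3,
    outcome_weights = c(Uncertain = 0.05, Recovered = 0.48,
                        Improved = 0.46, Unimproved = 0.01,
                        WithSequelae = 0, Death = 0)) {
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    sex_proportion_female = sex_proportion_female,
    age_band_weights = age_band_weights,
    height_mean_cm = height_mean_cm, height_sd_cm = height_sd_cm,
    weight_mean_kg = weight_mean_kg, weight_sd_kg = weight_sd_kg,
    missing_rate = missing_rate,
    drug_catalog = tibble::as_tibble(drug_catalog),
    target_pt_code = as.character(target_pt_code),
    baseline_event_logodds = baseline_event_logodds,
    covariate_effects = covariate_effects,
    drug_effects = drug_effects,
    onset_models = onset_models,
    background_onset = background_onset,
    date_window = as.character(date_window),
    start_date_missing_rate = start_date_missing_rate,
    onset_date_missing_rate = onset_date_missing_rate,
    outcome_weights = outcome_weights
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

# Collects every violation and reports them together.
validate_sim_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  chk(is.numeric(cfg$n_cases) && cfg$n_cases >= 1, "n_cases must be >= 1")
  prob01 <- function(p) all(is.finite(p)) && all(p >= 0) && all(p <= 1)
  chk(prob01(cfg$sex_proportion_female),
      "sex_proportion_female must lie in [0, 1]")
  chk(prob01(cfg$missing_rate) && all(cfg$missing_rate < 1),
      "missing_rate entries must lie in [0, 1)")
  chk(setequal(names(cfg$missing_rate), c("sex", "age", "height", "weight")),
      "missing_rate must name sex, age, height, weight")
  chk(prob01(cfg$age_band_weights) &&
        abs(sum(cfg$age_band_weights) - 1) < 1e-9,
      "age_band_weights must be probabilities summing to 1")
  chk(all(names(cfg$age_band_weights) %in% .age_bands),
      "age_band_weights names must be decade bands <10 ... 100-109")
  chk(prob01(cfg$outcome_weights) && abs(sum(cfg$outcome_weights) - 1) < 1e-9,
      "outcome_weights must be probabilities summing to 1")
  chk(setequal(names(cfg$outcome_weights), .outcome_levels),
      "outcome_weights must name the six outcome categories")
  chk(all(c("drug_name", "exposure_probability") %in%
            names(cfg$drug_catalog)),
      "drug_catalog needs columns drug_name, exposure_probability")
  chk(prob01(cfg$drug_catalog$exposure_probability),
      "exposure probabilities must lie in [0, 1]")
  chk(!anyDuplicated(cfg$drug_catalog$drug_name),
      "drug_catalog names must be unique")
  chk(all(names(cfg$drug_effects) %in% cfg$drug_catalog$drug_name),
      "every drug in drug_effects must appear in drug_catalog")
  chk(all(names(cfg$onset_models) %in% cfg$drug_catalog$drug_name),
      "every drug in onset_models must appear in drug_catalog")
  ab_ok <- vapply(c(cfg$onset_models, list(cfg$background_onset)),
                  function(m) length(m) == 2 && all(is.finite(m)) &&
                    all(m > 0), logical(1))
  chk(all(ab_ok), "Weibull alpha and beta must be strictly positive")
  chk(prob01(cfg$start_date_missing_rate) && prob01(cfg$onset_date_missing_rate),
      "date missingness rates must lie in [0, 1]")
  chk(length(cfg$date_window) == 2 &&
        all(grepl("^\\d{8}$", cfg$date_window)) &&
        !is.na(parse_date8(cfg$date_window[1])) &&
        !is.na(parse_date8(cfg$date_window[2])) &&
        parse_date8(cfg$date_window[1]) <= parse_date8(cfg$date_window[2]),
      "date_window must be two ordered YYYYMMDD dates")
  chk(setequal(names(cfg$covariate_effects),
               c("female", "age_ge60", "obese", "underweight")),
      "covariate_effects must name female, age_ge60, obese, underweight")

  if (length(errs)) {
    stop(paste0("invalid simulation config:\n",
                paste0("  - ", errs, collapse = "\n")), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Reads a YAML document whose keys mirror the [sim_config()] arguments and
#' validates it. Nested mappings (e.g. `onset_models`) are converted to the
#' in-memory forms; omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$drug_catalog)) {
    y$drug_catalog <- tibble::tibble(
      drug_name = vapply(y$drug_catalog, function(d) d$drug_name, ""),
      exposure_probability = vapply(y$drug_catalog,
                                    function(d) d$exposure_probability, 0))
  }
  for (nm in c("age_band_weights", "missing_rate", "covariate_effects",
               "drug_effects", "outcome_weights", "height_mean_cm",
               "height_sd_cm", "weight_mean_kg", "weight_sd_kg",
               "background_onset")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  if (!is.null(y$onset_models)) {
    y$onset_models <- lapply(y$onset_models, unlist)
  }
  if (!is.null(y$date_window)) y$date_window <- as.character(unlist(y$date_window))
  do.call(sim_config, y)
}

degrade_dates <- function(dates8, rate) {
  n <- length(dates8)
  u <- stats::runif(n)
  out <- dates8
  partial <- u < rate / 2
  blank <- u >= rate / 2 & u < rate
  out[partial] <- substr(out[partial], 1, 6)
  out[blank] <- ""
  out
}

#' Generate synthetic JADER-layout tables with ground truth
#'
#' For each case the generator samples sex and age band, latent continuous
#' height/weight (banded into 10-unit ranges), independent drug exposures
#' with uniform start dates, and the target event from a logistic model in
#' the banded covariates plus drug effects. When the event fires, its onset
#' date is the start date of one randomly chosen exposed effect drug plus a
#' Weibull latency rounded up to whole days (a configured background
#' latency covers events with no exposed effect drug). Demographic fields
#' and dates are then degraded by the configured missingness. The same seed
#' and config always reproduce identical tables.
#'
#' @param config a `sim_config`.
#' @return List of class `srs_simulation` with elements `data` (a
#'   `jader_data` object) and `truth` (the per-case and per-drug ground
#'   truth; see [ground_truth_summary()]).
#' @export
simulate_srs <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cases
  case_id <- sprintf("SIM%07d", seq_len(n))

  sex <- ifelse(stats::runif(n) < config$sex_proportion_female,
                "female", "male")
  age_band <- sample(names(config$age_band_weights), n, replace = TRUE,
                     prob = unname(config$age_band_weights))
  hm <- unname(config$height_mean_cm[sex])
  hs <- unname(config$height_sd_cm[sex])
  wm <- unname(config$weight_mean_kg[sex])
  ws <- unname(config$weight_sd_kg[sex])
  height <- pmax(stats::rnorm(n, hm, hs), 100)
  weight <- pmax(stats::rnorm(n, wm, ws), 10)
  h_lo <- floor(height / 10) * 10
  w_lo <- floor(weight / 10) * 10
  height_band <- sprintf("%d-%d", as.integer(h_lo), as.integer(h_lo + 9))
  weight_band <- sprintf("%d-%d", as.integer(w_lo), as.integer(w_lo + 9))

  # covariates exactly as the pipeline will compute them from the bands
  ebmi <- compute_ebmi(height_band, weight_band)
  ebmi_class <- classify_ebmi(ebmi)
  age_ge60 <- band_lower(age_band) >= 60

  catalog <- config$drug_catalog
  n_drugs <- nrow(catalog)
  exposed <- matrix(stats::runif(n * n_drugs), n, n_drugs) <
    matrix(catalog$exposure_probability, n, n_drugs, byrow = TRUE)
  colnames(exposed) <- catalog$drug_name

  win <- as.integer(parse_date8(config$date_window))
  start_num <- matrix(NA_integer_, n, n_drugs,
                      dimnames = list(NULL, catalog$drug_name))
  n_expo <- sum(exposed)
  start_num[exposed] <- as.integer(floor(stats::runif(n_expo, win[1],
                                                      win[2] + 1)))

  ce <- config$covariate_effects
  lp <- config$baseline_event_logodds +
    ce[["female"]] * (sex == "female") +
    ce[["age_ge60"]] * age_ge60 +
    ce[["obese"]] * (ebmi_class == "obese") +
    ce[["underweight"]] * (ebmi_class == "underweight")
  de <- config$drug_effects
  if (length(de)) {
    lp <- lp + as.vector(exposed[, names(de), drop = FALSE] %*% unname(de))
  }
  p_event <- stats::plogis(lp)
  event <- stats::runif(n) < p_event

  # onset: pick one exposed effect drug as the carrier, add Weibull latency
  effect_drugs <- names(config$onset_models)
  carrier <- rep(NA_character_, n)
  latency <- rep(NA_real_, n)
  onset_num <- rep(NA_integer_, n)
  ev_idx <- which(event)
  for (i in ev_idx) {
    carriers <- effect_drugs[exposed[i, effect_drugs, drop = TRUE]]
    if (length(carriers)) {
      d <- if (length(carriers) == 1L) carriers else sample(carriers, 1L)
      m <- config$onset_models[[d]]
      carrier[i] <- d
      latency[i] <- ceiling(stats::rweibull(1, shape = m[["beta"]],
                                            scale = m[["alpha"]]))
      onset_num[i] <- start_num[i, d] + latency[i]
    } else {
      m <- config$background_onset
      latency[i] <- ceiling(stats::rweibull(1, shape = m[["beta"]],
                                            scale = m[["alpha"]]))
      base <- exposed[i, , drop = TRUE]
      if (any(base)) {
        j <- which(base)
        j <- if (length(j) == 1L) j else sample(j, 1L)
        onset_num[i] <- start_num[i, j] + latency[i]
      } else {
        onset_num[i] <- as.integer(floor(stats::runif(1, win[1],
                                                      win[2] + 1))) +
          latency[i]
      }
    }
  }

  # DRUG table
  idx <- which(exposed, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  roles <- sample(c("suspected", "concomitant", "unknown"), nrow(idx),
                  replace = TRUE, prob = c(0.5, 0.45, 0.05))
  drug_start <- format_date8(as.Date(start_num[idx], origin = "1970-01-01"))
  drug_start <- degrade_dates(drug_start, config$start_date_missing_rate)
  drug_tbl <- tibble::tibble(
    case_id = case_id[idx[, 1]],
    drug_name = catalog$drug_name[idx[, 2]],
    role = roles,
    start_date = drug_start,
    end_date = ""
  )

  # REAC table: one target row per event case, one background noise row per
  # non-event case (every report carries at least one reaction)
  outcome_all <- sample(names(config$outcome_weights), n, replace = TRUE,
                        prob = unname(config$outcome_weights))
  onset_chr <- format_date8(as.Date(onset_num, origin = "1970-01-01"))
  onset_chr[is.na(onset_num)] <- ""
  onset_chr[event] <- degrade_dates(onset_chr[event],
                                    config$onset_date_missing_rate)
  noise_codes <- sprintf("1000%04d", 1:5)
  noise_pick <- sample(5L, n, replace = TRUE)
  noise_onset <- format_date8(as.Date(
    as.integer(floor(stats::runif(n, win[1], win[2] + 1))),
    origin = "1970-01-01"))
  noise_onset <- degrade_dates(noise_onset, config$onset_date_missing_rate)
  reac_tbl <- tibble::tibble(
    case_id = case_id,
    pt_code = ifelse(event, config$target_pt_code, noise_codes[noise_pick]),
    pt_name = ifelse(event, "Colitis microscopic",
                     sprintf("Background event %d", noise_pick)),
    onset_date = ifelse(event, onset_chr, noise_onset),
    outcome = outcome_all
  )

  # DEMO table with field-level missingness applied after truth is fixed
  demo_tbl <- tibble::tibble(
    case_id = case_id, sex = sex, age_band = age_band,
    height_band = height_band, weight_band = weight_band)
  mr <- config$missing_rate
  demo_tbl$sex[stats::runif(n) < mr[["sex"]]] <- ""
  demo_tbl$age_band[stats::runif(n) < mr[["age"]]] <- ""
  demo_tbl$height_band[stats::runif(n) < mr[["height"]]] <- ""
  demo_tbl$weight_band[stats::runif(n) < mr[["weight"]]] <- ""

  hist_tbl <- tibble::tibble(case_id = case_id, history_term = "")

  data <- structure(
    list(demo = demo_tbl, drug = drug_tbl, reac = reac_tbl, hist = hist_tbl,
         report = list(n_cases = n, n_drug_rows = nrow(drug_tbl),
                       n_reac_rows = nrow(reac_tbl),
                       orphan_drug = 0L, orphan_reac = 0L,
                       n_bad_outcome = 0L)),
    class = "jader_data")

  exposure_counts <- colSums(exposed)
  true_or <- rep(1, n_drugs)
  names(true_or) <- catalog$drug_name
  if (length(de)) true_or[names(de)] <- exp(unname(de))
  drug_truth <- tibble::tibble(
    drug = catalog$drug_name,
    exposure_probability = catalog$exposure_probability,
    true_or = unname(true_or),
    weibull_alpha = vapply(catalog$drug_name, function(d) {
      m <- config$onset_models[[d]]
      if (is.null(m)) NA_real_ else m[["alpha"]]
    }, 0),
    weibull_beta = vapply(catalog$drug_name, function(d) {
      m <- config$onset_models[[d]]
      if (is.null(m)) NA_real_ else m[["beta"]]
    }, 0),
    n_exposed = as.integer(unname(exposure_counts))
  )

  truth <- list(
    config = config,
    cases = tibble::tibble(
      case_id = case_id, sex = sex, age_band = age_band,
      latent_height_cm = height, latent_weight_kg = weight,
      latent_bmi = weight / (height / 100)^2,
      ebmi = ebmi, ebmi_class = ebmi_class, age_ge60 = age_ge60,
      event_probability = as.numeric(p_event), event = event,
      carrier_drug = carrier, latency_days = latency),
    drugs = drug_truth
  )

  structure(list(data = data, truth = truth), class = "srs_simulation")
}

#' @export
print.srs_simulation <- function(x, ...) {
  cat("<srs_simulation>\n")
  cat(sprintf("  %d cases, %d target-event cases (%s)\n",
              nrow(x$truth$cases), sum(x$truth$cases$event),
              x$truth$config$target_pt_code))
  cat(sprintf("  %d catalog drugs, %d with injected effects\n",
              nrow(x$truth$drugs), sum(x$truth$drugs$true_or != 1)))
  invisible(x)
}

#' Summarize the injected ground truth
#'
#' Per-drug table of the generative truth behind a simulation: the injected
#' odds ratio (1 for null drugs), the Weibull onset parameters where
#' configured, and the realized exposure count.
#'
#' @param truth the `truth` element of a [simulate_srs()] result (or the
#'   result itself).
#' @return Tibble `drug`, `exposure_probability`, `true_or`,
#'   `weibull_alpha`, `weibull_beta`, `n_exposed`.
#' @export
ground_truth_summary <- function(truth) {
  if (inherits(truth, "srs_simulation")) truth <- truth$truth
  stopifnot(is.list(truth), !is.null(truth$drugs))
  truth$drugs
}
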