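null_config <- function(n = 1000, seed = 1, baseline = stats::qlogis(0.1),
                        drug_effects = stats::setNames(numeric(0),
                                                       character(0)),
                        onset_models = list(), ...) {
  sim_config(
    n_cases = n, seed = seed,
    missing_rate = c(sex = 0, age = 0, height = 0, weight = 0),
    baseline_event_logodds = baseline,
    covariate_effects = c(female = 0, age_ge60 = 0, obese = 0,
                          underweight = 0),
    drug_effects = drug_effects,
    onset_models = onset_models,
    start_date_missing_rate = 0, onset_date_missing_rate = 0,
    ...)
}

test_that("identical seed and config reproduce identical tables", {
  cfg <- sim_config(n_cases = 500, seed = 11)
  s1 <- simulate_srs(cfg)
  s2 <- simulate_srs(cfg)
  for (tab in c("demo", "drug", "reac", "hist")) {
    expect_identical(s1$data[[tab]], s2$data[[tab]])
  }
  s3 <- simulate_srs(sim_config(n_cases = 500, seed = 12))
  expect_false(identical(s1$data$demo, s3$data$demo))
})

test_that("config validation reports all violations at once", {
  err <- tryCatch(
    sim_config(sex_proportion_female = 1.5,
               drug_effects = c(notadrug = log(2)),
               outcome_weights = c(Uncertain = 1, Recovered = 1,
                                   Improved = 0, Unimproved = 0,
                                   WithSequelae = 0, Death = 0)),
    error = function(e) conditionMessage(e))
  expect_match(err, "sex_proportion_female")
  expect_match(err, "drug_catalog")
  expect_match(err, "outcome_weights")
})

test_that("event counts follow the configured baseline rate", {
  counts <- sapply(1:5, function(s) {
    cfg <- null_config(n = 1000, seed = s,
                       drug_catalog = tibble::tibble(
                         drug_name = character(0),
                         exposure_probability = numeric(0)))
    sim <- simulate_srs(cfg)
    # the configured rate is hit exactly, report by report
    expect_equal(sim$truth$cases$event_probability, rep(0.1, 1000))
    sum(sim$truth$cases$event)
  })
  # binomial oracle: mean count over replicates within 3 standard errors
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(1000 * 0.1 * 0.9 / 5))
})

test_that("with all effects zero the event rate is independent of sex", {
  sim <- simulate_srs(null_config(n = 5000, seed = 5))
  tc <- sim$truth$cases
  p <- tapply(tc$event, tc$sex, mean)
  n <- tapply(tc$event, tc$sex, length)
  pool <- mean(tc$event)
  z <- (p[["female"]] - p[["male"]]) /
    sqrt(pool * (1 - pool) * (1 / n[["female"]] + 1 / n[["male"]]))
  expect_lt(abs(z), 1.96)
})

test_that("an injected odds ratio is recovered from the raw 2x2 table", {
  cfg <- null_config(n = 20000, seed = 9, baseline = stats::qlogis(0.02),
                     drug_catalog = tibble::tibble(
                       drug_name = "drugX", exposure_probability = 0.1),
                     drug_effects = c(drugX = log(35)),
                     onset_models = list(drugX = c(alpha = 100, beta = 1)))
  sim <- simulate_srs(cfg)
  tc <- sim$truth$cases
  exposed <- tc$case_id %in%
    sim$data$drug$case_id[sim$data$drug$drug_name == "drugX"]
  a <- sum(tc$event & exposed);  b <- sum(tc$event & !exposed)
  cc <- sum(!tc$event & exposed); d <- sum(!tc$event & !exposed)
  or <- (a * d) / (b * cc)
  ci <- exp(log(or) + c(-1, 1) * 1.96 * sqrt(1/a + 1/b + 1/cc + 1/d))
  expect_gt(35, ci[1])
  expect_lt(35, ci[2])
})

test_that("bands contain their latent values and onsets follow starts", {
  sim <- shared_run()
  tc <- sim$truth$cases
  # banding inverse: every emitted band contains its latent value
  demo <- sim$data$demo
  has_h <- nzchar(demo$height_band)
  h <- srssignal:::parse_band(demo$height_band[has_h])
  lat_h <- tc$latent_height_cm[match(demo$case_id[has_h], tc$case_id)]
  expect_true(all(lat_h >= h$lo & lat_h < h$hi + 1))
  has_w <- nzchar(demo$weight_band)
  w <- srssignal:::parse_band(demo$weight_band[has_w])
  lat_w <- tc$latent_weight_kg[match(demo$case_id[has_w], tc$case_id)]
  expect_true(all(lat_w >= w$lo & lat_w < w$hi + 1))

  # carrier-drug onset dates never precede the drug start date
  ev <- tc[tc$event & !is.na(tc$carrier_drug), ]
  drug <- sim$data$drug
  reac <- sim$data$reac
  onset <- srssignal:::parse_date8(
    reac$onset_date[match(ev$case_id, reac$case_id)])
  key <- paste(drug$case_id, drug$drug_name)
  start <- srssignal:::parse_date8(
    drug$start_date[match(paste(ev$case_id, ev$carrier_drug), key)])
  ok <- !is.na(onset) & !is.na(start)
  expect_true(all(onset[ok] >= start[ok]))
  expect_true(all(ev$latency_days >= 1))
})

test_that("ground-truth summary reflects the injected effects", {
  sim <- simulate_srs(null_config(n = 2000, seed = 21))
  gt <- ground_truth_summary(sim)
  expect_true(all(gt$true_or == 1))

  cfg <- null_config(n = 2000, seed = 22,
                     drug_effects = c(lansoprazole = log(2)),
                     onset_models = list(lansoprazole = c(alpha = 50,
                                                          beta = 1)))
  sim2 <- simulate_srs(cfg)
  gt2 <- ground_truth_summary(sim2)
  expect_equal(sum(gt2$true_or != 1), 1L)
  expect_equal(gt2$true_or[gt2$drug == "lansoprazole"], 2)

  # realized exposure equals the distinct-case count in the DRUG table
  per_drug <- table(unique(sim2$data$drug[c("case_id", "drug_name")])$drug_name)
  for (d in names(per_drug)) {
    expect_equal(gt2$n_exposed[gt2$drug == d], as.integer(per_drug[[d]]))
  }
})

test_that("a YAML config round-trips through read_sim_config", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_cases = 100, seed = 4, sex_proportion_female = 0.5,
    drug_catalog = list(list(drug_name = "drugA",
                             exposure_probability = 0.2)),
    drug_effects = list(drugA = log(3)),
    onset_models = list(drugA = list(alpha = 60, beta = 1.2))), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_cases, 100L)
  expect_equal(cfg$drug_catalog$drug_name, "drugA")
  expect_equal(unname(cfg$drug_effects["drugA"]), log(3))
  expect_equal(cfg$onset_models$drugA[["alpha"]], 60)
})
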