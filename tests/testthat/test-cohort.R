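test_that("intermediate values follow the lower-bound-plus-5 rule", {
  expect_equal(intermediate_value("160-169"), 165)
  expect_equal(intermediate_value("50-59"), 55)
  expect_equal(intermediate_value("40-49"), 45)
  expect_error(intermediate_value("160-170"), "unparseable")
  expect_error(intermediate_value("tall"), "unparseable")
})

test_that("eBMI matches the worked band arithmetic", {
  expect_equal(compute_ebmi("160-169", "50-59"), 20.2)
  expect_equal(compute_ebmi("150-159", "40-49"), round(45 / 1.55^2, 1))
  # strictly increasing in weight at fixed height
  weights <- c("10-19", "30-39", "50-59", "70-79", "90-99")
  vals <- compute_ebmi(rep("170-179", 5), weights)
  expect_true(all(diff(vals) > 0))
})

test_that("eBMI classes use half-open intervals exactly as stated", {
  expect_equal(classify_ebmi(c(18.4, 18.5, 20.2, 24.99, 25.0)),
               c("underweight", "normal", "normal", "normal", "obese"))
})

test_that("boxplot bounds match a direct (n+1)p quartile computation", {
  vals <- c(1:10, 100)
  q1 <- oracle_quantile_np1(vals, 0.25)
  q3 <- oracle_quantile_np1(vals, 0.75)
  b <- ebmi_outlier_bounds(vals)
  expect_equal(unname(b), c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1)))
  expect_true(100 > b["high"])           # the outlier is excluded
  expect_true(all(1:10 >= b["low"] & 1:10 <= b["high"]))

  # identical values: bounds collapse, nothing excluded
  b0 <- ebmi_outlier_bounds(rep(21.5, 6))
  expect_equal(unname(b0), c(21.5, 21.5))

  # idempotence: applying the frozen bounds to already-inside values
  inside <- vals[vals >= b["low"] & vals <= b["high"]]
  b2 <- ebmi_outlier_bounds(inside)
  expect_true(all(inside >= b2["low"] & inside <= b2["high"]))

  expect_error(ebmi_outlier_bounds(1:3), "at least 4")
})

test_that("analysis-table construction applies exclusions in order", {
  # 10 bundles: 3 with missing fields, 1 pooled eBMI outlier -> 6 retained
  demo <- rbind(
    demo_row("A1", height = "150-159", weight = "40-49"),  # 18.7
    demo_row("A2", height = "150-159", weight = "50-59"),  # 22.9
    demo_row("A3", height = "160-169", weight = "50-59"),  # 20.2
    demo_row("A4", height = "160-169", weight = "60-69"),  # 23.9
    demo_row("A5", height = "170-179", weight = "60-69"),  # 21.2
    demo_row("A6", height = "170-179", weight = "70-79"),  # 24.5
    demo_row("A7", height = "100-109", weight = "90-99"),  # 86.2 outlier
    demo_row("M1", sex = ""),
    demo_row("M2", age = ""),
    demo_row("M3", weight = ""))
  drug <- drug_row(paste0("A", 1:7))
  reac <- rbind(reac_row("A1"), reac_row("A2", pt = "10000001"))
  jd <- read_fixture(write_fixture_csvs(demo, drug, reac))
  at <- build_analysis_table(jd)
  fc <- at$flowchart
  expect_equal(fc[["n_input"]], 10)
  expect_equal(fc[["n_excluded_missing"]], 3)
  expect_equal(fc[["n_input"]],
               fc[["n_excluded_missing"]] + fc[["n_complete"]])
  expect_equal(fc[["n_excluded_outlier"]], 1)
  expect_equal(fc[["n_analysis"]], 6)
  expect_equal(fc[["n_event"]], 1)
  expect_true(all(at$cases$ebmi_class ==
                    classify_ebmi(at$cases$ebmi)))
  expect_equal(at$cases$event, at$cases$case_id == "A1")
})

test_that("age stratification uses the band lower bound", {
  demo <- rbind(demo_row("B1", age = "50-59"), demo_row("B2", age = "60-69"),
                demo_row("B3", age = "100-109"), demo_row("B4", age = "<10"))
  jd <- read_fixture(write_fixture_csvs(demo, drug_row("B1"),
                                        reac_row("B1", pt = "10000001")))
  at <- build_analysis_table(jd)
  expect_equal(at$cases$age_ge60[match(paste0("B", 1:4), at$cases$case_id)],
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("time-to-onset keeps the shortest fully dated duration", {
  demo <- demo_row(c("T1", "T2", "T3", "T4"))
  drug <- rbind(
    drug_row("T1", start = "20200101"),                 # 72 days
    drug_row("T2", start = "20200213"),                 # 30 days
    drug_row("T2", start = "20200101"),                 # 72 days, same drug
    drug_row("T3", start = "20200401"),                 # onset before start
    drug_row("T4", start = "20200314"),                 # same day -> 0.5
    drug_row("T4", drug = "aspirin", start = "202003")) # partial, ignored
  reac <- rbind(reac_row("T1", onset = "20200313"),
                reac_row("T2", onset = "20200314"),
                reac_row("T3", onset = "20200313"),
                reac_row("T4", onset = "20200314"))
  jd <- read_fixture(write_fixture_csvs(demo, drug, reac))
  at <- build_analysis_table(jd)
  tto <- build_tto_table(at)
  get <- function(id) tto$duration_days[tto$case_id == id]
  expect_equal(get("T1"), 72)
  expect_equal(get("T2"), 30)   # shortest of {30, 72}
  expect_length(get("T3"), 0)   # negative dropped
  expect_equal(attr(tto, "n_negative_dropped"), 1L)
  expect_equal(get("T4"), 0.5)  # zero-day onset mapped to 0.5
  expect_true(all(tto$duration_days > 0))
  expect_equal(attr(tto, "n_tto"), 3L)
})

test_that("drugs of interest respect the threshold and strata", {
  n_ev <- c(drugA = 4, drugB = 5, drugC = 9, drugD = 10, drugE = 19,
            drugF = 20, drugG = 100, drugH = 128)
  ids <- sprintf("E%03d", seq_len(130))
  demo <- demo_row(ids)
  reac <- reac_row(ids)
  drug <- do.call(rbind, lapply(names(n_ev), function(d) {
    drug_row(ids[seq_len(n_ev[[d]])], drug = d)
  }))
  jd <- read_fixture(write_fixture_csvs(demo, drug, reac))
  at <- build_analysis_table(jd)
  doi <- drugs_of_interest(at)
  expect_false("drugA" %in% doi$drug)  # 4 cases: below threshold
  strata <- setNames(doi$stratum, doi$drug)
  expect_equal(strata[["drugB"]], "5-9")
  expect_equal(strata[["drugC"]], "5-9")
  expect_equal(strata[["drugD"]], "10-19")
  expect_equal(strata[["drugE"]], "10-19")
  expect_equal(strata[["drugF"]], "20-100")
  expect_equal(strata[["drugG"]], "20-100")
  expect_equal(strata[["drugH"]], ">100")
})

test_that("outcome tabulation counts the six categories", {
  demo <- demo_row(c("O1", "O2", "O3", "O4"))
  reac <- rbind(reac_row("O1", outcome = "Recovered"),
                reac_row("O2", outcome = "Recovered"),
                reac_row("O3", outcome = "Death"),
                reac_row("O4", pt = "10000001", outcome = "Improved"))
  jd <- read_fixture(write_fixture_csvs(demo, drug_row("O1"), reac))
  at <- build_analysis_table(jd)
  oc <- tabulate_outcomes(at)
  expect_equal(oc$n[oc$outcome == "Recovered"], 2L)
  expect_equal(oc$n[oc$outcome == "Death"], 1L)
  expect_equal(sum(oc$n), sum(at$cases$event))  # conservation, none missing

  # no event cases -> all zeros
  at0 <- build_analysis_table(jd, target_pt_code = "99999999")
  expect_true(all(tabulate_outcomes(at0)$n == 0L))
})

test_that("synthetic eBMI class mostly agrees with the latent BMI class", {
  sim <- shared_run()$truth
  lat <- classify_ebmi(sim$cases$latent_bmi)
  agree <- mean(lat == sim$cases$ebmi_class)
  expect_gt(agree, 0.8)  # banding error only
})
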