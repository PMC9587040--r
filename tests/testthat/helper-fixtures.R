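# Fixtures are built in code at test time: small CSV tables written to a
# temp dir, and one memoized 20,000-case synthetic run shared across files.

write_fixture_csvs <- function(demo, drug, reac, hist = NULL, dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(hist)) {
    hist <- data.frame(case_id = demo$case_id, history_term = "")
  }
  utils::write.csv(demo, file.path(dir, "demo.csv"), row.names = FALSE)
  utils::write.csv(drug, file.path(dir, "drug.csv"), row.names = FALSE)
  utils::write.csv(reac, file.path(dir, "reac.csv"), row.names = FALSE)
  utils::write.csv(hist, file.path(dir, "hist.csv"), row.names = FALSE)
  dir
}

read_fixture <- function(dir) {
  read_jader_tables(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
                    file.path(dir, "reac.csv"), file.path(dir, "hist.csv"))
}

demo_row <- function(id, sex = "female", age = "70-79", height = "150-159",
                     weight = "50-59") {
  data.frame(case_id = id, sex = sex, age_band = age, height_band = height,
             weight_band = weight)
}

drug_row <- function(id, drug = "lansoprazole", role = "suspected",
                     start = "20200101", end = "") {
  data.frame(case_id = id, drug_name = drug, role = role,
             start_date = start, end_date = end)
}

reac_row <- function(id, pt = "10056979", name = "Colitis microscopic",
                     onset = "20200301", outcome = "Recovered") {
  data.frame(case_id = id, pt_code = pt, pt_name = name, onset_date = onset,
              outcome = outcome)
}

# a small ready-made dataset: 3 complete cases, case C1 has the target event
tiny_jader <- function() {
  demo <- rbind(demo_row("C1"), demo_row("C2", sex = "male"),
                demo_row("C3", age = "40-49"))
  drug <- rbind(drug_row("C1"), drug_row("C1", drug = "aspirin"),
                drug_row("C2"), drug_row("C2", drug = "aspirin"),
                drug_row("C3", drug = "aspirin"))
  reac <- rbind(reac_row("C1"),
                reac_row("C2", pt = "10000001", name = "Background event 1"),
                reac_row("C3", pt = "10000001", name = "Background event 1"))
  read_fixture(write_fixture_csvs(demo, drug, reac))
}

# memoized default-condition synthetic run shared by several test files
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(run_config(simulation = sim_config(), seed = 42L))
    }
    cache
  }
})

# hand-coded (n + 1) p order-statistic quantile, independent of
# stats::quantile, used as the oracle for the package quantile rule
oracle_quantile_np1 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  pos <- (n + 1) * p
  lo <- floor(pos)
  if (lo < 1) return(s[1])
  if (lo >= n) return(s[n])
  s[lo] + (pos - lo) * (s[lo + 1] - s[lo])
}
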