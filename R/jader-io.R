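# Reading, validating and writing JADER-layout spontaneous-report tables.

#' Canonical JADER-layout schema
#'
#' Column names expected in the four CSV tables. Real JADER extracts use
#' Japanese headers and tokens; translate them first (see
#' [jader_alias_map()]) — the package operates on this English canonical
#' schema only.
#'
#' @return Named list of character vectors (one per table).
#' @export
jader_schema <- function() {
  list(
    demo = c("case_id", "sex", "age_band", "height_band", "weight_band"),
    drug = c("case_id", "drug_name", "role", "start_date", "end_date"),
    reac = c("case_id", "pt_code", "pt_name", "onset_date", "outcome"),
    hist = c("case_id", "history_term")
  )
}

.outcome_levels <- c("Uncertain", "Recovered", "Improved", "Unimproved",
                     "WithSequelae", "Death")
.role_levels <- c("suspected", "concomitant", "interacting", "unknown")

#' Header and token translations for raw JADER extracts
#'
#' A documented alias map from the Japanese column headers and value tokens
#' used in the PMDA distribution to the canonical English schema, so a real
#' extract can be ingested after header translation. The map is a starting
#' point, not a complete localization: extend `headers` / `tokens` for
#' distribution versions with different wording.
#'
#' @return List with elements `headers` (named character; names are the
#'   Japanese headers) and `tokens` (named character; names are Japanese
#'   value tokens, values the canonical tokens; `"不明"` ("unknown")
#'   maps to the empty string, i.e. missing).
#' @export
jader_alias_map <- function() {
  list(
    headers = c(
      "識別番号" = "case_id",          # identification number
      "性別" = "sex",                          # sex
      "年齢" = "age_band",                     # age
      "身長" = "height_band",                  # height
      "体重" = "weight_band",                  # weight
      "医薬品（一般名）" = "drug_name",
      "医薬品の関与" = "role",
      "投与開始日" = "start_date",
      "投与終了日" = "end_date",
      "有害事象" = "pt_name",
      "発現日" = "onset_date",
      "転帰" = "outcome",
      "原疾患等" = "history_term"
    ),
    tokens = c(
      "男性" = "male",
      "女性" = "female",
      "不明" = "",
      "被疑薬" = "suspected",
      "併用薬" = "concomitant",
      "相互作用" = "interacting",
      "回復" = "Recovered",
      "軽快" = "Improved",
      "未回復" = "Unimproved",
      "後遺症あり" = "WithSequelae",
      "死亡" = "Death"
    )
  )
}

read_csv_chr <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8", na.strings = character(0))
}

apply_aliases <- function(df, aliases) {
  if (is.null(aliases)) return(df)
  hd <- aliases$headers
  nm <- names(df)
  hit <- nm %in% names(hd)
  names(df)[hit] <- unname(hd[nm[hit]])
  tk <- aliases$tokens
  if (length(tk)) {
    for (j in seq_along(df)) {
      v <- df[[j]]
      m <- v %in% names(tk)
      if (any(m)) df[[j]][m] <- unname(tk[v[m]])
    }
  }
  df
}

check_schema <- function(df, expected, table) {
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s table: missing column(s) %s",
                 table, paste(sQuote(missing), collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df[expected])
}

#' Read the four JADER-layout tables
#'
#' Reads `demo`, `drug`, `reac` and (optionally) `hist` CSVs, validates the
#' header schema, and joins them into one case-keyed object. DRUG/REAC rows
#' whose `case_id` does not appear in DEMO are counted as orphans and
#' reported — never silently dropped. HIST is parsed for schema validation
#' only and not attached to cases, mirroring the distribution in which the
#' history table lacks the report-ID link used elsewhere.
#'
#' @param demo_path,drug_path,reac_path,hist_path paths to the CSV tables
#'   (`hist_path` may be `NULL`).
#' @param aliases optional alias map (see [jader_alias_map()]) applied to
#'   headers and value tokens before validation.
#' @return An object of class `jader_data`: a list with tibbles `demo`,
#'   `drug`, `reac`, `hist` and a `report` list (row counts, orphan counts,
#'   count of unrecognized outcome tokens coerced to missing).
#' @export
read_jader_tables <- function(demo_path, drug_path, reac_path,
                              hist_path = NULL, aliases = NULL) {
  sch <- jader_schema()
  demo <- check_schema(apply_aliases(read_csv_chr(demo_path), aliases),
                       sch$demo, "DEMO")
  drug <- check_schema(apply_aliases(read_csv_chr(drug_path), aliases),
                       sch$drug, "DRUG")
  reac <- check_schema(apply_aliases(read_csv_chr(reac_path), aliases),
                       sch$reac, "REAC")
  hist <- NULL
  if (!is.null(hist_path)) {
    hist <- check_schema(apply_aliases(read_csv_chr(hist_path), aliases),
                         sch$hist, "HIST")
  }

  if (any(!nzchar(demo$case_id))) {
    stop("integrity error: empty case_id in DEMO table", call. = FALSE)
  }
  dup <- unique(demo$case_id[duplicated(demo$case_id)])
  if (length(dup)) {
    stop(sprintf("integrity error: duplicate DEMO case_id %s",
                 paste(sQuote(utils::head(dup, 5)), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(drug) == 0L) {
    warning("DRUG table is empty: all cases will have empty drug lists",
            call. = FALSE)
  }

  orphan_drug <- sum(!drug$case_id %in% demo$case_id)
  orphan_reac <- sum(!reac$case_id %in% demo$case_id)

  bad_outcome <- !reac$outcome %in% c(.outcome_levels, "")
  n_bad_outcome <- sum(bad_outcome)
  if (n_bad_outcome) {
    warning(sprintf("%d REAC row(s) with unrecognized outcome token treated as missing",
                    n_bad_outcome), call. = FALSE)
    reac$outcome[bad_outcome] <- ""
  }

  structure(
    list(
      demo = demo, drug = drug, reac = reac, hist = hist,
      report = list(
        n_cases = nrow(demo),
        n_drug_rows = nrow(drug),
        n_reac_rows = nrow(reac),
        orphan_drug = orphan_drug,
        orphan_reac = orphan_reac,
        n_bad_outcome = n_bad_outcome
      )
    ),
    class = "jader_data"
  )
}

#' @export
print.jader_data <- function(x, ...) {
  cat("<jader_data>\n")
  cat(sprintf("  cases (DEMO): %d\n", x$report$n_cases))
  cat(sprintf("  DRUG rows: %d (orphans: %d)\n",
              x$report$n_drug_rows, x$report$orphan_drug))
  cat(sprintf("  REAC rows: %d (orphans: %d)\n",
              x$report$n_reac_rows, x$report$orphan_reac))
  invisible(x)
}

#' Number of cases (distinct DEMO reports)
#' @param x a `jader_data` object.
#' @return integer count.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "jader_data"))
  x$report$n_cases
}

#' Assemble the case bundle for one report
#'
#' Returns the joined view of one report: its DEMO row plus all DRUG and
#' REAC rows sharing the `case_id`.
#'
#' @param x a `jader_data` object.
#' @param case_id a single report identifier present in DEMO.
#' @return List with elements `demo` (one-row tibble), `drugs`, `reactions`.
#' @export
case_bundle <- function(x, case_id) {
  stopifnot(inherits(x, "jader_data"), length(case_id) == 1L)
  if (!case_id %in% x$demo$case_id) {
    stop(sprintf("unknown case_id %s", sQuote(case_id)), call. = FALSE)
  }
  list(
    demo = x$demo[x$demo$case_id == case_id, ],
    drugs = x$drug[x$drug$case_id == case_id, ],
    reactions = x$reac[x$reac$case_id == case_id, ]
  )
}

#' Write JADER-layout tables back to CSV
#'
#' Inverse of [read_jader_tables()]; emits the canonical four CSVs so
#' synthetic datasets can be materialized on disk.
#'
#' @param x a `jader_data` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_jader_tables <- function(x, dir) {
  stopifnot(inherits(x, "jader_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.csv"),
             drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"),
             hist = file.path(dir, "hist.csv"))
  utils::write.csv(x$demo, paths["demo"], row.names = FALSE, quote = TRUE)
  utils::write.csv(x$drug, paths["drug"], row.names = FALSE, quote = TRUE)
  utils::write.csv(x$reac, paths["reac"], row.names = FALSE, quote = TRUE)
  hist <- x$hist
  if (is.null(hist)) {
    hist <- tibble::tibble(case_id = character(0), history_term = character(0))
  }
  utils::write.csv(hist, paths["hist"], row.names = FALSE, quote = TRUE)
  invisible(paths)
}

write_tsv_fixed <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the consolidated report tables
#'
#' Emits the deterministic, byte-stable TSV outputs of a pipeline run:
#' `flowchart.tsv`, `drug_groups.tsv`, `ror_screen.tsv`, `tto_summary.tsv`,
#' `regression_all.tsv`, `regression_by_sex.tsv`. Numeric columns are
#' rendered at fixed precision (reporting odds ratios and confidence bounds
#' to 2 decimals, eBMI and day quantities to 1 decimal, shape parameters to
#' 2, p-values to 3) so identical results always produce identical bytes.
#'
#' @param results a pipeline result (class `srs_run`, see [run_pipeline()])
#'   or a named list with any of the components `flowchart`, `drug_groups`,
#'   `ror_screen`, `tto_summary`, `regression_all`, `regression_by_sex`
#'   (tibbles in the documented column layouts).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, named character vector of file paths written.
#' @export
write_report_tables <- function(results, out_dir) {
  if (inherits(results, "srs_run")) results <- results$tables
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory %s", sQuote(out_dir)),
           call. = FALSE)
    }
  }
  written <- character(0)
  emit <- function(name, df) {
    p <- file.path(out_dir, name)
    write_tsv_fixed(df, p)
    written[[name]] <<- p
  }

  if (!is.null(results$flowchart)) {
    fc <- results$flowchart
    emit("flowchart.tsv",
         data.frame(stage = fc$stage, count = as.integer(fc$count)))
  }
  if (!is.null(results$drug_groups)) {
    dg <- results$drug_groups
    emit("drug_groups.tsv",
         data.frame(stratum = dg$stratum, drug = dg$drug,
                    n_cases = as.integer(dg$n_cases)))
  }
  if (!is.null(results$ror_screen)) {
    rs <- results$ror_screen
    emit("ror_screen.tsv", data.frame(
      drug = rs$drug, a = as.integer(rs$a), b = as.integer(rs$b),
      c = as.integer(rs$c), d = as.integer(rs$d),
      ror = fmt_fixed(rs$ror, 2),
      ci_low = fmt_fixed(rs$ci_low, 2), ci_high = fmt_fixed(rs$ci_high, 2),
      signal = rs$signal, defined = rs$defined))
  }
  if (!is.null(results$tto_summary)) {
    ts <- results$tto_summary
    emit("tto_summary.tsv", data.frame(
      drug = ts$drug, n = as.integer(ts$n),
      median = fmt_fixed(ts$median, 1),
      q1 = fmt_fixed(ts$q1, 1), q3 = fmt_fixed(ts$q3, 1),
      alpha = fmt_fixed(ts$alpha, 1),
      alpha_ci_low = fmt_fixed(ts$alpha_ci_low, 1),
      alpha_ci_high = fmt_fixed(ts$alpha_ci_high, 1),
      beta = fmt_fixed(ts$beta, 2),
      beta_ci_low = fmt_fixed(ts$beta_ci_low, 2),
      beta_ci_high = fmt_fixed(ts$beta_ci_high, 2),
      failure_type = ts$failure_type, converged = ts$converged))
  }
  reg_df <- function(rt) data.frame(
    population = rt$population, term = rt$term,
    cases_with_term = as.integer(rt$cases_with_term),
    noncases_with_term = as.integer(rt$noncases_with_term),
    coefficient = fmt_fixed(rt$coefficient, 4), se = fmt_fixed(rt$se, 4),
    aror = fmt_fixed(rt$aror, 2),
    ci_low = fmt_fixed(rt$ci_low, 2), ci_high = fmt_fixed(rt$ci_high, 2),
    p_value = fmt_fixed(rt$p_value, 3), vif = fmt_fixed(rt$vif, 2),
    forced = rt$forced, selected = rt$selected)
  if (!is.null(results$regression_all)) {
    emit("regression_all.tsv", reg_df(results$regression_all))
  }
  if (!is.null(results$regression_by_sex)) {
    emit("regression_by_sex.tsv", reg_df(results$regression_by_sex))
  }
  invisible(written)
}
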