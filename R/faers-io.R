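#' @noRd
outcome_codes <- function() {
  c("death" = "DE", "life-threatening" = "LT", "hospitalization" = "HO",
    "disability" = "DS", "congenital anomaly" = "CA",
    "required intervention" = "RI", "other serious" = "OT")
}

faers_tables <- c("DEMO", "DRUG", "REAC", "OUTC", "THER")

#' Write a report_set in the FAERS quarterly ASCII layout
#'
#' Emits the five dollar-sign-delimited tables of the quarterly layout,
#' each with a header row and one record per line; missing fields are
#' empty strings and dates are ISO-8601 (`YYYY-MM-DD`). Column dialect
#' (documented here, round-tripped by [read_reports()]):
#'
#' * `DEMO.txt` — `primaryid$sex$age$reporter_country$event_dt$rept_yr`
#'   (sex coded `M`/`F`)
#' * `DRUG.txt` — `primaryid$drug_seq$drugname`
#' * `THER.txt` — `primaryid$drug_seq$start_dt$end_dt`
#' * `REAC.txt` — `primaryid$pt`
#' * `OUTC.txt` — `primaryid$outc_cod` (codes `DE`, `LT`, `HO`, `DS`,
#'   `CA`, `RI`, `OT`)
#'
#' If the set carries a generator ledger it is written alongside as
#' `generator_ledger.json`.
#'
#' @param reports A non-empty [report_set()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_faers_layout <- function(reports, directory) {
  stopifnot(inherits(reports, "report_set"))
  if (n_reports(reports) == 0) stop("empty report_set", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  }

  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  blank <- function(x) ifelse(is.na(x), "", as.character(x))

  demo_out <- tibble::tibble(
    primaryid = reports$demo$report_id,
    sex = dplyr::case_match(reports$demo$sex, "male" ~ "M", "female" ~ "F",
                            .default = ""),
    age = blank(reports$demo$age),
    reporter_country = blank(reports$demo$country),
    event_dt = fmt_date(reports$demo$event_date),
    rept_yr = blank(reports$demo$reporting_year))
  drug_out <- tibble::tibble(
    primaryid = reports$drug$report_id,
    drug_seq = reports$drug$drug_seq,
    drugname = reports$drug$name)
  ther_out <- tibble::tibble(
    primaryid = reports$drug$report_id,
    drug_seq = reports$drug$drug_seq,
    start_dt = fmt_date(reports$drug$start_date),
    end_dt = fmt_date(reports$drug$end_date))
  reac_out <- tibble::tibble(primaryid = reports$reac$report_id,
                             pt = reports$reac$pt)
  outc_out <- tibble::tibble(
    primaryid = reports$outc$report_id,
    outc_cod = unname(outcome_codes()[reports$outc$outcome]))

  tables <- list(DEMO = demo_out, DRUG = drug_out, REAC = reac_out,
                 OUTC = outc_out, THER = ther_out)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(directory, paste0(nm, ".txt"))
    readr::write_delim(tables[[nm]], path, delim = "$", na = "")
    paths <- c(paths, path)
  }
  led <- attr(reports, "ledger")
  if (!is.null(led)) {
    led_path <- file.path(directory, "generator_ledger.json")
    jsonlite::write_json(led, led_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, led_path)
  }
  invisible(paths)
}

#' Read FAERS-layout tables into a report_set
#'
#' Reads the five dollar-delimited tables written by [write_faers_layout()]
#' (or equivalently formatted extracts) and joins the child tables on the
#' report identifier. Unparseable dates and empty fields become missing
#' values — rows are never silently dropped for a bad date. Lines with the
#' wrong number of fields are skipped with a warning giving the count.
#'
#' @param directory Directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `THER.txt`.
#' @return A [report_set()].
#' @export
read_reports <- function(directory) {
  paths <- file.path(directory, paste0(faers_tables, ".txt"))
  names(paths) <- faers_tables
  missing <- faers_tables[!file.exists(paths)]
  if (length(missing) > 0) {
    stop(sprintf("missing mandatory table(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  read_tbl <- function(path, col_types) {
    tbl <- withCallingHandlers(
      readr::read_delim(path, delim = "$", col_types = col_types,
                        na = c(""), progress = FALSE),
      warning = function(w) {
        if (grepl("parsing issues", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    probs <- readr::problems(tbl)
    if (nrow(probs) > 0) {
      ## problems() reports file line numbers; line 1 is the header
      bad_rows <- unique(probs$row) - 1L
      bad_rows <- bad_rows[bad_rows >= 1 & bad_rows <= nrow(tbl)]
      warning(sprintf("%s: skipped %d malformed line(s)", basename(path),
                      length(bad_rows)), call. = FALSE)
      tbl <- tbl[-bad_rows, , drop = FALSE]
    }
    tbl
  }
  parse_date <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")

  demo_raw <- read_tbl(paths["DEMO"], "ccdccc")
  drug_raw <- read_tbl(paths["DRUG"], "cic")
  reac_raw <- read_tbl(paths["REAC"], "cc")
  outc_raw <- read_tbl(paths["OUTC"], "cc")
  ther_raw <- read_tbl(paths["THER"], "cicc")

  demo <- tibble::tibble(
    report_id = demo_raw$primaryid,
    sex = dplyr::case_match(demo_raw$sex, "M" ~ "male", "F" ~ "female",
                            .default = NA_character_),
    age = demo_raw$age,
    country = demo_raw$reporter_country,
    reporting_year = suppressWarnings(as.integer(demo_raw$rept_yr)),
    event_date = parse_date(demo_raw$event_dt))

  drug <- dplyr::left_join(
    tibble::tibble(report_id = drug_raw$primaryid,
                   drug_seq = drug_raw$drug_seq,
                   name = drug_raw$drugname),
    tibble::tibble(report_id = ther_raw$primaryid,
                   drug_seq = ther_raw$drug_seq,
                   start_date = parse_date(ther_raw$start_dt),
                   end_date = parse_date(ther_raw$end_dt)),
    by = c("report_id", "drug_seq"))
  if (!"start_date" %in% names(drug)) drug$start_date <- as.Date(NA)
  if (!"end_date" %in% names(drug)) drug$end_date <- as.Date(NA)

  code_to_level <- stats::setNames(names(outcome_codes()), outcome_codes())
  outc <- tibble::tibble(
    report_id = outc_raw$primaryid,
    outcome = unname(code_to_level[outc_raw$outc_cod]))
  outc <- outc[!is.na(outc$outcome), , drop = FALSE]

  reac <- tibble::tibble(report_id = reac_raw$primaryid, pt = reac_raw$pt)

  ## drop orphan child rows (their parent DEMO line was malformed/skipped)
  keep_children <- function(tbl) {
    tbl[tbl$report_id %in% demo$report_id, , drop = FALSE]
  }
  report_set(demo, keep_children(drug), keep_children(reac),
             keep_children(outc))
}
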