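#' In-memory set of spontaneous safety reports
#'
#' A `report_set` holds one cohort of spontaneous adverse-event reports as
#' four relational tibbles keyed by `report_id`, mirroring the DEMO / DRUG
#' (+ therapy dates) / REAC / OUTC structure of the FAERS quarterly files:
#'
#' * `demo` — one row per report: `report_id`, `sex` (`"male"`, `"female"`
#'   or `NA`), `age` (years), `country`, `reporting_year`, `event_date`.
#' * `drug` — one row per drug entry: `report_id`, `drug_seq`, `name`,
#'   `start_date`, `end_date`.
#' * `reac` — one row per reaction: `report_id`, `pt` (MedDRA preferred
#'   term, free text).
#' * `outc` — one row per outcome code: `report_id`, `outcome`, one of
#'   `outcome_levels()`.
#'
#' Missing values are `NA`; no imputation is ever performed.
#'
#' @param demo,drug,reac,outc Tibbles as described above.
#' @return An object of class `report_set`.
#' @export
report_set <- function(demo, drug, reac, outc) {
  demo <- tibble::as_tibble(demo)
  drug <- tibble::as_tibble(drug)
  reac <- tibble::as_tibble(reac)
  outc <- tibble::as_tibble(outc)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(demo, c("report_id", "sex", "age", "country", "reporting_year",
               "event_date"), "demo")
  need(drug, c("report_id", "drug_seq", "name", "start_date", "end_date"),
       "drug")
  need(reac, c("report_id", "pt"), "reac")
  need(outc, c("report_id", "outcome"), "outc")

  if (anyDuplicated(demo$report_id) > 0) {
    stop("report_id must be unique within a report_set", call. = FALSE)
  }
  if (any(demo$age < 0, na.rm = TRUE)) {
    stop("age must be non-negative", call. = FALSE)
  }
  bad_out <- setdiff(unique(outc$outcome), outcome_levels())
  if (length(bad_out) > 0) {
    stop(sprintf("unknown outcome level(s): %s",
                 paste(bad_out, collapse = ", ")), call. = FALSE)
  }
  both <- !is.na(drug$start_date) & !is.na(drug$end_date)
  if (any(drug$end_date[both] < drug$start_date[both])) {
    stop("drug end_date earlier than start_date", call. = FALSE)
  }
  for (child in list(drug, reac, outc)) {
    if (!all(child$report_id %in% demo$report_id)) {
      stop("child table references unknown report_id", call. = FALSE)
    }
  }
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc),
            class = "report_set")
}

#' Recognised seriousness outcome levels
#'
#' The seven regulatory outcome codes carried by spontaneous reports, in
#' decreasing severity order (the order used when a multi-coded record must
#' be assigned a single level).
#'
#' @return Character vector of the seven levels.
#' @export
outcome_levels <- function() {
  c("death", "life-threatening", "disability", "hospitalization",
    "congenital anomaly", "required intervention", "other serious")
}

#' Number of reports in a report_set
#' @param reports A `report_set`.
#' @return Integer count of reports (DEMO rows).
#' @export
n_reports <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  nrow(reports$demo)
}

#' Restrict a report_set to a subset of reports
#'
#' Keeps the selected reports (and their drug/reaction/outcome rows) in the
#' original order; all generator ledger attributes are dropped.
#'
#' @param reports A `report_set`.
#' @param keep Logical vector along `reports$demo` rows, or a character
#'   vector of report ids.
#' @return A `report_set`.
#' @export
filter_reports <- function(reports, keep) {
  stopifnot(inherits(reports, "report_set"))
  ids <- if (is.logical(keep)) {
    stopifnot(length(keep) == n_reports(reports))
    reports$demo$report_id[keep]
  } else {
    as.character(keep)
  }
  report_set(
    demo = reports$demo[reports$demo$report_id %in% ids, , drop = FALSE],
    drug = reports$drug[reports$drug$report_id %in% ids, , drop = FALSE],
    reac = reports$reac[reports$reac$report_id %in% ids, , drop = FALSE],
    outc = reports$outc[reports$outc$report_id %in% ids, , drop = FALSE]
  )
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf(
    "<report_set> %d reports | %d drug entries | %d reactions | %d outcome codes\n",
    nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$outc)))
  yrs <- range(x$demo$reporting_year, na.rm = TRUE)
  cat(sprintf("  reporting years %s-%s\n", yrs[1], yrs[2]))
  invisible(x)
}
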