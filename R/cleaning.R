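#' Normalize a drug name for matching and deduplication
#'
#' Case-folds, trims, collapses internal whitespace, and — when a lexicon
#' is supplied — maps any synonym (brand or generic) to the lexicon's
#' canonical name, which also strips salt/formulation suffixes listed as
#' synonyms.
#'
#' @param x Character vector of drug names.
#' @param lexicon Optional [drug_lexicon()].
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x, lexicon = NULL) {
  out <- gsub("\\s+", " ", trimws(tolower(x)))
  if (!is.null(lexicon)) {
    hit <- out %in% lexicon$synonyms
    out[hit] <- lexicon$canonical
  }
  out
}

normalize_pt <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' @noRd
cleaning_report <- function(n_input, n_duplicates_removed,
                            n_aberrant_removed, n_retained) {
  rep <- list(n_input = as.integer(n_input),
              n_duplicates_removed = as.integer(n_duplicates_removed),
              n_aberrant_removed = as.integer(n_aberrant_removed),
              n_retained = as.integer(n_retained))
  if (rep$n_input !=
      rep$n_duplicates_removed + rep$n_aberrant_removed + rep$n_retained) {
    stop("cleaning report does not partition the input", call. = FALSE)
  }
  structure(rep, class = "cleaning_report")
}

#' Combine sequential cleaning reports into one partition
#'
#' @param dedup,aberrant `cleaning_report`s from [deduplicate()] and
#'   [remove_aberrant()] run in sequence.
#' @return A single `cleaning_report` partitioning the original input.
#' @export
combine_cleaning_reports <- function(dedup, aberrant) {
  stopifnot(inherits(dedup, "cleaning_report"),
            inherits(aberrant, "cleaning_report"),
            dedup$n_retained == aberrant$n_input)
  cleaning_report(dedup$n_input, dedup$n_duplicates_removed,
                  aberrant$n_aberrant_removed, aberrant$n_retained)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d in | %d duplicates removed | %d aberrant removed | %d retained\n",
    x$n_input, x$n_duplicates_removed, x$n_aberrant_removed, x$n_retained))
  invisible(x)
}

## Full dedup key per report. A record missing any key field gets NA
## (missing never equals missing, so such records are never merged).
dedup_keys <- function(reports) {
  demo <- reports$demo
  norm_names <- normalize_drug_name(reports$drug$name)
  drug_sig <- paste(norm_names, "|",
                    ifelse(is.na(reports$drug$start_date), "??",
                           format(reports$drug$start_date)), "|",
                    ifelse(is.na(reports$drug$end_date), "??",
                           format(reports$drug$end_date)))
  drug_missing_any <- is.na(reports$drug$start_date) |
    is.na(reports$drug$end_date)
  agg_sorted <- function(values, ids) {
    sp <- split(values, factor(ids, levels = demo$report_id))
    vapply(sp, function(v) paste(sort(unique(v)), collapse = ";"),
           character(1))
  }
  drug_key <- agg_sorted(drug_sig, reports$drug$report_id)
  drug_miss <- vapply(split(drug_missing_any,
                            factor(reports$drug$report_id,
                                   levels = demo$report_id)),
                      function(v) length(v) == 0 || any(v), logical(1))
  reac_key <- agg_sorted(normalize_pt(reports$reac$pt),
                         reports$reac$report_id)
  outc_key <- agg_sorted(reports$outc$outcome, reports$outc$report_id)

  has_missing <- is.na(demo$sex) | is.na(demo$age) | is.na(demo$country) |
    is.na(demo$event_date) | is.na(demo$reporting_year) |
    drug_miss | reac_key == "" | outc_key == ""

  key <- paste(demo$sex, trunc(demo$age), demo$country,
               format(demo$event_date), demo$reporting_year,
               drug_key, reac_key, outc_key, sep = "\x1f")
  list(key = key, has_missing = has_missing)
}

#' Remove duplicated reports by the full record key
#'
#' Two reports are duplicates when they agree on the entire key: sex,
#' age (truncated to whole years), country of reporter, event date,
#' reporting year, the set of normalized drug names with their start and
#' end dates, the set of reaction preferred terms, and the set of outcome
#' codes. Among records sharing a key only the first in input order is
#' retained; records missing any key field are never merged. The operation
#' is idempotent and permuting the input changes which representative
#' survives but not the counts.
#'
#' @param reports A [report_set()].
#' @return List with `reports` (deduplicated set, input order preserved)
#'   and `report` (a `cleaning_report` with `n_aberrant_removed = 0`).
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  kk <- dedup_keys(reports)
  is_dup <- duplicated(kk$key) & !kk$has_missing
  ## a later record can only be a duplicate of an earlier *complete* record
  ## with the same key; since a complete key cannot collide with a missing
  ## one (missing fields poison the key with NA), duplicated() suffices
  kept <- filter_reports(reports, !is_dup)
  list(reports = kept,
       report = cleaning_report(n_reports(reports), sum(is_dup), 0,
                                n_reports(kept)))
}

#' Exclude reports whose target-drug start date postdates the event
#'
#' A report is aberrant — and excluded — if and only if both the earliest
#' start date across its target-drug entries and the event date are
#' present, and the start date is strictly later than the event date.
#' Reports with either date missing are retained (no imputation).
#'
#' @param reports A [report_set()].
#' @param lexicon [drug_lexicon()] identifying the target drug.
#' @return List with `reports` (retained set) and `report` (a
#'   `cleaning_report` with `n_duplicates_removed = 0`).
#' @export
remove_aberrant <- function(reports, lexicon) {
  stopifnot(inherits(reports, "report_set"))
  tto <- time_to_onset(reports, lexicon)
  aberrant <- !is.na(tto$days) & tto$days < 0
  kept <- filter_reports(reports, !aberrant)
  list(reports = kept,
       report = cleaning_report(n_reports(reports), 0, sum(aberrant),
                                n_reports(kept)))
}

#' Time from target-drug start to event onset
#'
#' Day difference between the event date and the earliest start date among
#' the report's target-drug entries; missing when either date is absent.
#' Negative values indicate aberrant date ordering and no longer occur
#' after [remove_aberrant()].
#'
#' @param reports A [report_set()].
#' @param lexicon [drug_lexicon()] identifying the target drug.
#' @return Tibble `report_id`, `days` (integer or `NA`), one row per
#'   report in input order.
#' @export
time_to_onset <- function(reports, lexicon) {
  stopifnot(inherits(reports, "report_set"))
  drug <- reports$drug
  is_target <- normalize_drug_name(drug$name, lexicon) == lexicon$canonical
  target_rows <- drug[is_target & !is.na(drug$start_date), , drop = FALSE]
  sp <- split(as.integer(target_rows$start_date),
              factor(target_rows$report_id,
                     levels = reports$demo$report_id))
  earliest <- vapply(sp, function(v) if (length(v) == 0) NA_integer_
                     else min(v), integer(1))
  days <- as.integer(reports$demo$event_date) - earliest
  tibble::tibble(report_id = reports$demo$report_id,
                 days = as.integer(days))
}
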