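#' Disproportionality analysis for the total and per-category events
#'
#' Computes one [signal_estimate()] row for total cardiovascular events
#' (union of the eight categories) and one per category, against the full
#' background of the supplied (cleaned) report set. Per-category analyses
#' keep reports of the other categories in the background.
#'
#' @param reports A cleaned [report_set()].
#' @param lexicon Target-drug [drug_lexicon()].
#' @param smq_map PT-to-SMQ map tibble (`pt`, `smq_code`).
#' @param registry Category registry, default [smq_registry()]; categories
#'   absent from the map get `n = 0` rows.
#' @param ror_variant,ic_method Passed to [signal_estimate()].
#' @return Tibble with columns `category`, `smq_code`, then the
#'   [signal_estimate()] columns; first row is the total.
#' @export
run_category_analysis <- function(reports, lexicon, smq_map,
                                  registry = smq_registry(),
                                  ror_variant = "odds_ratio",
                                  ic_method = "approx") {
  stopifnot(inherits(reports, "report_set"))
  is_drug <- match_drug(reports, lexicon)
  assignment <- assign_categories(reports, smq_map)
  one <- function(label, code, flag) {
    est <- signal_estimate(build_table(reports, is_drug, flag),
                           ror_variant = ror_variant,
                           ic_method = ic_method)
    dplyr::bind_cols(tibble::tibble(category = label, smq_code = code), est)
  }
  rows <- list(one("total", NA_integer_, assignment$is_cardiovascular))
  for (i in seq_len(nrow(registry))) {
    rows[[i + 1]] <- one(registry$name[i], registry$smq_code[i],
                         category_flag(reports, assignment,
                                       registry$smq_code[i]))
  }
  dplyr::bind_rows(rows)
}

#' Cumulative information-component time series
#'
#' For each requested year the estimate is computed on the cumulative
#' subset of reports with `reporting_year <= year`, the estimation scheme
#' under which interval width narrows as evidence accumulates. A year in
#' which the cumulative subset holds no target-drug report is emitted with
#' `n = 0` and flagged unusable.
#'
#' @param reports A cleaned [report_set()].
#' @param lexicon Target-drug [drug_lexicon()].
#' @param smq_map PT-to-SMQ map.
#' @param smq_code Single category code, or `NULL` for total
#'   cardiovascular events.
#' @param years Integer years; default the sorted reporting years present.
#' @param ror_variant,ic_method Passed to [signal_estimate()].
#' @return Tibble with `year`, `n_cumulative_reports`, `usable`, and the
#'   [signal_estimate()] columns.
#' @export
ic_time_series <- function(reports, lexicon, smq_map, smq_code = NULL,
                           years = NULL, ror_variant = "odds_ratio",
                           ic_method = "approx") {
  stopifnot(inherits(reports, "report_set"))
  if (is.null(years)) {
    years <- sort(unique(reports$demo$reporting_year))
  }
  rows <- lapply(years, function(y) {
    sub <- filter_reports(reports, !is.na(reports$demo$reporting_year) &
                            reports$demo$reporting_year <= y)
    base <- tibble::tibble(year = as.integer(y),
                           n_cumulative_reports = n_reports(sub))
    if (n_reports(sub) == 0 || !any(match_drug(sub, lexicon))) {
      return(dplyr::bind_cols(base, tibble::tibble(
        usable = FALSE, n = 0L, expected = NA_real_, ic = NA_real_,
        ic025 = NA_real_, ic975 = NA_real_, ror = NA_real_,
        ror025 = NA_real_, ror975 = NA_real_, signal = FALSE)))
    }
    assignment <- assign_categories(sub, smq_map)
    flag <- if (is.null(smq_code)) assignment$is_cardiovascular
            else category_flag(sub, assignment, smq_code)
    est <- signal_estimate(build_table(sub, match_drug(sub, lexicon), flag),
                           ror_variant = ror_variant,
                           ic_method = ic_method)
    dplyr::bind_cols(base, tibble::tibble(usable = TRUE), est)
  })
  dplyr::bind_rows(rows)
}

#' Stratified disproportionality analysis (sex by age group)
#'
#' Within each stratum both the cases and the background are restricted to
#' the stratum before the table is built, and the signal rule is applied
#' per stratum-category pair. Reports missing a stratum variable are
#' excluded from that stratification; empty strata are skipped with a
#' warning.
#'
#' @param reports A cleaned [report_set()].
#' @param lexicon,smq_map,registry As in [run_category_analysis()].
#' @param age_cutoff Years separating the younger / older groups
#'   (default 65, the conventional geriatric cutoff).
#' @param ror_variant,ic_method Passed through.
#' @return Tibble of [run_category_analysis()] rows with leading `sex`
#'   and `age_group` columns.
#' @export
stratified_analysis <- function(reports, lexicon, smq_map,
                                registry = smq_registry(), age_cutoff = 65,
                                ror_variant = "odds_ratio",
                                ic_method = "approx") {
  stopifnot(inherits(reports, "report_set"))
  demo <- reports$demo
  age_group <- ifelse(is.na(demo$age), NA_character_,
                      ifelse(demo$age < age_cutoff,
                             sprintf("<%d", age_cutoff),
                             sprintf(">=%d", age_cutoff)))
  rows <- list()
  for (sx in c("male", "female")) {
    for (ag in c(sprintf("<%d", age_cutoff), sprintf(">=%d", age_cutoff))) {
      keep <- !is.na(demo$sex) & demo$sex == sx &
        !is.na(age_group) & age_group == ag
      if (!any(keep)) {
        warning(sprintf("stratum %s / %s is empty; skipped", sx, ag),
                call. = FALSE)
        next
      }
      sub <- filter_reports(reports, keep)
      res <- run_category_analysis(sub, lexicon, smq_map, registry,
                                   ror_variant = ror_variant,
                                   ic_method = ic_method)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(sex = sx, age_group = ag,
                       .rows = nrow(res)), res)
    }
  }
  dplyr::bind_rows(rows)
}

#' Disproportionality analysis on a restricted background
#'
#' Sensitivity analysis in which the whole computation — cases and
#' non-cases alike — is repeated inside a subpopulation (for instance,
#' reports whose indication matches the drug's main use), so that
#' disproportionality is measured against comparators with a similar risk
#' profile rather than the entire database.
#'
#' @param reports A cleaned [report_set()].
#' @param lexicon,smq_map,registry As in [run_category_analysis()].
#' @param background_predicate Logical vector along reports, or a function
#'   of the report set returning one; must select a non-empty background.
#' @param ror_variant,ic_method Passed through.
#' @return As [run_category_analysis()], computed on the restriction.
#' @export
restricted_background_analysis <- function(reports, lexicon, smq_map,
                                           background_predicate,
                                           registry = smq_registry(),
                                           ror_variant = "odds_ratio",
                                           ic_method = "approx") {
  stopifnot(inherits(reports, "report_set"))
  keep <- if (is.function(background_predicate)) {
    background_predicate(reports)
  } else {
    background_predicate
  }
  stopifnot(is.logical(keep), length(keep) == n_reports(reports))
  if (!any(keep)) stop("restriction selects an empty background",
                       call. = FALSE)
  run_category_analysis(filter_reports(reports, keep), lexicon, smq_map,
                        registry, ror_variant = ror_variant,
                        ic_method = ic_method)
}
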