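#' Percentage with two-decimal reporting convention
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @param digits Decimal places (default 2, the reporting convention).
#' @return `100 * numerator / denominator`, rounded.
#' @export
proportion_pct <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive",
                                  call. = FALSE)
  round(100 * numerator / denominator, digits)
}

#' Time-to-onset summary
#'
#' Median and quartiles of onset lags (quantile convention: linear
#' interpolation between order statistics, `stats::quantile()` type 7),
#' plus the cumulative proportions of events within the first month
#' (<= 30 days) and first three months (<= 90 days).
#'
#' @param tto_values Numeric days; `NA`s are excluded and counted out of
#'   `n_available`.
#' @return Tibble: `n_available`, `median`, `q1`, `q3`, `pct_30d`,
#'   `pct_90d` (all statistics `NA` when no value is available).
#' @export
tto_summary <- function(tto_values) {
  vals <- tto_values[!is.na(tto_values)]
  n <- length(vals)
  if (n == 0) {
    return(tibble::tibble(n_available = 0L, median = NA_real_,
                          q1 = NA_real_, q3 = NA_real_,
                          pct_30d = NA_real_, pct_90d = NA_real_))
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n_available = n, median = q[2], q1 = q[1], q3 = q[3],
    pct_30d = proportion_pct(sum(vals <= 30), n),
    pct_90d = proportion_pct(sum(vals <= 90), n))
}

#' Outcome-severity profile
#'
#' Distributes reports over the seven seriousness levels. A report with
#' several outcome codes contributes to exactly one level, the most severe
#' it carries (severity order [outcome_levels()]: death >
#' life-threatening > disability > hospitalization > congenital anomaly >
#' required intervention > other serious), so the level counts sum to the
#' number of reports with available outcome information — the denominator
#' of every percentage.
#'
#' @param reports A [report_set()].
#' @return Tibble: `outcome`, `n`, `pct` (over available outcomes), plus
#'   attribute-free `n_available` repeated per row.
#' @export
outcome_profile <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  lv <- outcome_levels()
  outc <- reports$outc
  worst <- integer(0)
  if (nrow(outc) > 0) {
    rank <- match(outc$outcome, lv)
    worst <- tapply(rank, outc$report_id, min)
  }
  n_avail <- length(worst)
  counts <- tabulate(unlist(worst), nbins = length(lv))
  tibble::tibble(
    outcome = lv, n = counts,
    pct = if (n_avail > 0) proportion_pct(counts, n_avail) else NA_real_,
    n_available = n_avail)
}

#' Baseline-characteristics table per category and total
#'
#' For the total cardiovascular cohort and each SMQ category: sex counts
#' and percentages, age mean / SD / range, reporting-year counts, reporter
#' country counts, the time-to-onset block ([tto_summary()]) and the
#' outcome block ([outcome_profile()]). Each block reports its own
#' "data available" denominator; percentages are computed against it.
#'
#' @param reports A cleaned [report_set()] already restricted to the
#'   cohort of interest (e.g. target-drug cardiovascular reports).
#' @param assignment [assign_categories()] result for `reports`.
#' @param lexicon Target-drug [drug_lexicon()] (anchors time-to-onset).
#' @param registry Category registry, default [smq_registry()].
#' @return Long tibble: `category`, `block`, `item`, `n`, `value`
#'   (`n` a count where the item is categorical, `value` a percentage or
#'   statistic).
#' @export
characteristics_table <- function(reports, assignment, lexicon,
                                  registry = smq_registry()) {
  stopifnot(inherits(reports, "report_set"))
  tto_all <- time_to_onset(reports, lexicon)

  one_block <- function(sub, label) {
    demo <- sub$demo
    out <- list()
    row <- function(block, item, n = NA_real_, value = NA_real_) {
      tibble::tibble(category = label, block = block, item = item,
                     n = as.numeric(n), value = as.numeric(value))
    }
    ## sex
    sex_avail <- sum(!is.na(demo$sex))
    for (sx in c("male", "female")) {
      cnt <- sum(demo$sex == sx, na.rm = TRUE)
      out[[length(out) + 1]] <- row(
        "sex", sx, cnt,
        if (sex_avail > 0) proportion_pct(cnt, sex_avail) else NA_real_)
    }
    out[[length(out) + 1]] <- row("sex", "data available", sex_avail)
    ## age
    ages <- demo$age[!is.na(demo$age)]
    out[[length(out) + 1]] <- row("age", "mean",
                                  value = if (length(ages)) mean(ages) else NA)
    out[[length(out) + 1]] <- row("age", "sd",
                                  value = if (length(ages) > 1)
                                    stats::sd(ages) else NA)
    out[[length(out) + 1]] <- row("age", "min",
                                  value = if (length(ages)) min(ages) else NA)
    out[[length(out) + 1]] <- row("age", "max",
                                  value = if (length(ages)) max(ages) else NA)
    out[[length(out) + 1]] <- row("age", "data available", length(ages))
    ## reporting year
    yr_avail <- sum(!is.na(demo$reporting_year))
    for (y in sort(unique(demo$reporting_year[!is.na(demo$reporting_year)]))) {
      cnt <- sum(demo$reporting_year == y, na.rm = TRUE)
      out[[length(out) + 1]] <- row("year", as.character(y), cnt,
                                    proportion_pct(cnt, yr_avail))
    }
    out[[length(out) + 1]] <- row("year", "data available", yr_avail)
    ## country
    ct_avail <- sum(!is.na(demo$country))
    for (ct in sort(unique(demo$country[!is.na(demo$country)]))) {
      cnt <- sum(demo$country == ct, na.rm = TRUE)
      out[[length(out) + 1]] <- row("country", ct, cnt,
                                    proportion_pct(cnt, ct_avail))
    }
    out[[length(out) + 1]] <- row("country", "data available", ct_avail)
    ## time to onset
    tto <- tto_summary(tto_all$days[match(demo$report_id,
                                          tto_all$report_id)])
    for (item in c("median", "q1", "q3", "pct_30d", "pct_90d")) {
      out[[length(out) + 1]] <- row("time_to_onset", item,
                                    value = tto[[item]])
    }
    out[[length(out) + 1]] <- row("time_to_onset", "data available",
                                  tto$n_available)
    ## outcome
    op <- outcome_profile(sub)
    for (i in seq_len(nrow(op))) {
      out[[length(out) + 1]] <- row("outcome", op$outcome[i], op$n[i],
                                    op$pct[i])
    }
    out[[length(out) + 1]] <- row("outcome", "data available",
                                  op$n_available[1])
    dplyr::bind_rows(out)
  }

  blocks <- list(one_block(reports, "total"))
  for (i in seq_len(nrow(registry))) {
    flag <- category_flag(reports, assignment, registry$smq_code[i])
    if (!any(flag)) next
    blocks[[length(blocks) + 1]] <- one_block(filter_reports(reports, flag),
                                              registry$name[i])
  }
  dplyr::bind_rows(blocks)
}
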