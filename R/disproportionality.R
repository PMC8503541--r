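#' 2x2 contingency table for one drug-event pair
#'
#' Cell counts against a background report set: `a` = reports with the
#' target drug and the event, `b` = drug without the event, `c` = event
#' without the drug, `d` = neither. Derived margins follow the
#' observed-to-expected convention: `n_drug = a + b`, `n_event = a + c`,
#' `n_total = a + b + c + d`, `n_observed = a`, and the expected count
#' under independence `n_expected = n_drug * n_event / n_total`.
#'
#' Cells are normally integer counts; non-integer cells are accepted
#' (tables reconstructed from published marginals are continuous).
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cells must be non-negative", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%s b=%s c=%s d=%s | E=%.2f\n",
              format(x$a), format(x$b), format(x$c), format(x$d),
              expected_count(x)))
  invisible(x)
}

#' Build the 2x2 table from report-level flags
#'
#' Each report falls in exactly one cell; the cells sum to the number of
#' reports. Flags may be logical vectors along the report set, or
#' predicate functions of the report set returning such vectors.
#'
#' @param reports A non-empty [report_set()].
#' @param drug_flag,event_flag Logical vectors or predicate functions.
#' @return A [contingency_table()].
#' @export
build_table <- function(reports, drug_flag, event_flag) {
  stopifnot(inherits(reports, "report_set"))
  n <- n_reports(reports)
  if (n == 0) stop("empty report_set", call. = FALSE)
  if (is.function(drug_flag)) drug_flag <- drug_flag(reports)
  if (is.function(event_flag)) event_flag <- event_flag(reports)
  stopifnot(length(drug_flag) == n, length(event_flag) == n)
  contingency_table(sum(drug_flag & event_flag),
                    sum(drug_flag & !event_flag),
                    sum(!drug_flag & event_flag),
                    sum(!drug_flag & !event_flag))
}

#' Expected count under independence
#'
#' @param table A [contingency_table()].
#' @return `n_drug * n_event / n_total`.
#' @export
expected_count <- function(table) {
  n_total <- table$a + table$b + table$c + table$d
  if (n_total == 0) stop("empty table", call. = FALSE)
  (table$a + table$b) * (table$a + table$c) / n_total
}

#' Shrunk information component with 95% interval
#'
#' The shrinkage-corrected information component
#' `IC = log2((a + 0.5) / (E + 0.5))` with `E` the expected count under
#' independence; the added 0.5 damps random fluctuation for rare events
#' and keeps the IC defined at `a = 0`. Interval methods:
#'
#' * `"approx"` (default) — the standard shrinkage-IC interval
#'   approximation,
#'   `IC025 = IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2` and
#'   `IC975 = IC + 2.4 (a+0.5)^-1/2 + 0.5 (a+0.5)^-3/2`;
#' * `"gamma"` — credible-interval quantiles of the gamma posterior
#'   `mu ~ Gamma(a + 0.5, E + 0.5)`, `IC = log2(mu)`.
#'
#' @param table A [contingency_table()].
#' @param method Interval method, `"approx"` or `"gamma"`.
#' @return Named numeric vector `ic`, `ic025`, `ic975` (bits).
#' @export
shrunk_ic <- function(table, method = c("approx", "gamma")) {
  method <- match.arg(method)
  a <- table$a
  e <- expected_count(table)
  ic <- log2((a + 0.5) / (e + 0.5))
  if (method == "approx") {
    ic025 <- ic - 3.3 * (a + 0.5)^-0.5 - 2 * (a + 0.5)^-1.5
    ic975 <- ic + 2.4 * (a + 0.5)^-0.5 + 0.5 * (a + 0.5)^-1.5
  } else {
    ic025 <- log2(stats::qgamma(0.025, shape = a + 0.5, rate = e + 0.5))
    ic975 <- log2(stats::qgamma(0.975, shape = a + 0.5, rate = e + 0.5))
  }
  c(ic = ic, ic025 = ic025, ic975 = ic975)
}

#' Reporting odds ratio with 95% interval
#'
#' Default variant: the classic reporting odds ratio with
#' Haldane-Anscombe continuity correction,
#' `ROR = ((a+0.5)(d+0.5)) / ((b+0.5)(c+0.5))`, with the log-normal
#' (Woolf) interval on the corrected cells. The `"observed_expected"`
#' variant instead reports `(a+0.5)/(E+0.5)` — identical to `2^IC` — with
#' its interval obtained as `2^` the IC interval; it is retained as a
#' configurable alternative observed-to-expected ratio scale.
#'
#' @param table A [contingency_table()].
#' @param variant `"odds_ratio"` (default) or `"observed_expected"`.
#' @param ic_method Passed to [shrunk_ic()] for the
#'   `"observed_expected"` interval.
#' @return Named numeric vector `ror`, `ror025`, `ror975`.
#' @export
ror_estimate <- function(table, variant = c("odds_ratio",
                                            "observed_expected"),
                         ic_method = "approx") {
  variant <- match.arg(variant)
  if (variant == "observed_expected") {
    ic <- shrunk_ic(table, method = ic_method)
    return(c(ror = unname(2^ic["ic"]), ror025 = unname(2^ic["ic025"]),
             ror975 = unname(2^ic["ic975"])))
  }
  a <- table$a + 0.5
  b <- table$b + 0.5
  c <- table$c + 0.5
  d <- table$d + 0.5
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, ror025 = ror * exp(-1.96 * se),
    ror975 = ror * exp(1.96 * se))
}

#' Apply the three-part signal rule
#'
#' A drug-event pair is a signal when the lower 95% bound of the ROR
#' exceeds 1, the lower 95% bound of the IC exceeds 0, and at least three
#' records carry the pair. All inequalities are strict: a lower bound
#' sitting exactly on its threshold is not a signal.
#'
#' @param ic025,ror025 Lower 95% bounds.
#' @param n Record count for the pair (cell `a`).
#' @return Logical.
#' @export
evaluate_signal <- function(ic025, ror025, n) {
  ic025 > 0 & ror025 > 1 & n >= 3
}

#' Full disproportionality estimate for one table
#'
#' @param table A [contingency_table()].
#' @param ror_variant,ic_method Passed to [ror_estimate()] and
#'   [shrunk_ic()].
#' @return One-row tibble: `n`, `expected`, `ic`, `ic025`, `ic975`,
#'   `ror`, `ror025`, `ror975`, `signal`.
#' @export
signal_estimate <- function(table, ror_variant = "odds_ratio",
                            ic_method = "approx") {
  ic_est <- shrunk_ic(table, method = ic_method)
  ror_est <- ror_estimate(table, variant = ror_variant,
                          ic_method = ic_method)
  tibble::tibble(
    n = table$a, expected = expected_count(table),
    ic = unname(ic_est["ic"]), ic025 = unname(ic_est["ic025"]),
    ic975 = unname(ic_est["ic975"]),
    ror = unname(ror_est["ror"]), ror025 = unname(ror_est["ror025"]),
    ror975 = unname(ror_est["ror975"]),
    signal = evaluate_signal(unname(ic_est["ic025"]),
                             unname(ror_est["ror025"]), table$a))
}

#' Reconstruct a 2x2 table from published marginals and a reporting odds
#' ratio
#'
#' Published disproportionality tables print the case count `a`, the drug
#' and database totals, and the estimates, but not the comparator event
#' count `c`. This solves for the (continuous) `c` at which the
#' continuity-corrected reporting odds ratio equals the printed value,
#' with `b = n_drug - a` and `d = n_total - n_drug - c`, allowing every
#' printed estimate to be recomputed from the printed row.
#'
#' @param a Case count for the pair.
#' @param n_drug Total reports mentioning the drug.
#' @param n_total Total reports in the database.
#' @param ror Printed reporting odds ratio.
#' @return A [contingency_table()] with non-integer `c`, `d`.
#' @export
reconstruct_table <- function(a, n_drug, n_total, ror) {
  stopifnot(a >= 0, n_drug >= a, n_total > n_drug, ror > 0)
  b <- n_drug - a
  f <- function(cc) {
    t <- contingency_table(a, b, cc, n_total - n_drug - cc)
    unname(ror_estimate(t)["ror"]) - ror
  }
  cc <- stats::uniroot(f, c(1e-9, n_total - n_drug - 1e-6),
                       tol = 1e-10)$root
  contingency_table(a, b, cc, n_total - n_drug - cc)
}
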