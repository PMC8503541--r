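#' Default drug catalog for the synthetic report stream
#'
#' A small polypharmacy catalog headed by the target proteasome inhibitor.
#' `prob` is the marginal probability that a report mentions the drug;
#' mentions are sampled independently per drug, so multi-drug reports arise
#' naturally. The target drug is given a marginal of 2%: large enough that
#' desk-scale cohorts contain hundreds of exposed reports, while keeping
#' the case/non-case contrast between exposed reports and a much larger
#' background, as in a national reporting database.
#'
#' @return Tibble with columns `name`, `prob`.
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    name = c("carfilzomib", "lenalidomide", "dexamethasone", "bortezomib",
             "daratumumab", "amlodipine", "metformin"),
    prob = c(0.02, 0.05, 0.08, 0.04, 0.03, 0.05, 0.06)
  )
}

#' Default event catalog for the synthetic report stream
#'
#' One row per (preferred term, SMQ category) membership; `smq_code` is `NA`
#' for background terms outside the eight cardiovascular SMQs. Marginal
#' probabilities are per-report baseline reporting rates before any
#' drug-event multiplier applies; cardiovascular terms are kept rare
#' (0.1-1.2%) against a common non-cardiac background, reproducing the
#' rare-event regime in which shrinkage matters.
#'
#' @return Tibble with columns `pt`, `prob`, `smq_code`.
#' @export
default_event_catalog <- function() {
  tibble::tribble(
    ~pt,                              ~prob, ~smq_code,
    "atrial fibrillation",            0.008, 20000049L,
    "ventricular tachycardia",        0.003, 20000049L,
    "cardiac failure",                0.006, 20000004L,
    "ejection fraction decreased",    0.004, 20000004L,
    "cardiomyopathy",                 0.004, 20000150L,
    "cardiac dysfunction",            0.004, 20000150L,
    "pulmonary embolism",             0.007, 20000081L,
    "deep vein thrombosis",           0.006, 20000081L,
    "hypertension",                   0.012, 20000147L,
    "blood pressure increased",       0.008, 20000147L,
    "myocardial infarction",          0.006, 20000043L,
    "angina pectoris",                0.003, 20000043L,
    "pulmonary hypertension",         0.003, 20000130L,
    "pulmonary arterial hypertension", 0.001, 20000130L,
    "electrocardiogram qt prolonged", 0.003, 20000001L,
    "torsade de pointes",             0.001, 20000001L,
    "nausea",                         0.060, NA,
    "fatigue",                        0.070, NA,
    "diarrhoea",                      0.050, NA,
    "pyrexia",                        0.040, NA,
    "drug ineffective",               0.050, NA
  )
}

#' Default drug-event association multipliers
#'
#' Relative reporting-rate ratios planted between the target drug and each
#' of the eight cardiovascular SMQ categories, set to the magnitudes
#' reported for carfilzomib in published FAERS disproportionality estimates
#' (reporting odds ratios between 1.4 and 2.8, strongest for cardiac
#' failure and pulmonary hypertension). `lambda = 1` means no association.
#'
#' @return Tibble with columns `drug`, `smq_code`, `lambda`.
#' @export
default_association_multipliers <- function() {
  tibble::tibble(
    drug = "carfilzomib",
    smq_code = c(20000049L, 20000004L, 20000150L, 20000081L,
                 20000147L, 20000043L, 20000130L, 20000001L),
    lambda = c(1.40, 2.79, 2.29, 1.67, 1.69, 1.55, 2.54, 1.44)
  )
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Full parameterization of the synthetic report stream. Defaults emulate
#' the 2015-2019 reporting-period conditions of the carfilzomib
#' cardiovascular safety analysis: a rare target drug in a polypharmacy
#' background, rare cardiovascular preferred terms grouped into the eight
#' narrow SMQs, planted association multipliers at the published magnitudes,
#' a right-skewed (log-normal, median 41 days) onset lag, and field-level
#' missingness at the rates implied by the published "data available"
#' denominators.
#'
#' @param n_reports Number of reports to emit (including duplicates).
#' @param drug_catalog Tibble `name`, `prob` of independent per-report
#'   mention probabilities.
#' @param event_catalog Tibble `pt`, `prob`, `smq_code` (one row per
#'   PT-category membership; `smq_code = NA` for background terms). Rows
#'   sharing a `pt` must share its `prob`.
#' @param association_multipliers Tibble `drug`, `smq_code`, `lambda`
#'   (positive reporting-rate ratios; `lambda = 1` is the null).
#' @param duplicate_fraction Fraction of emitted reports that are exact
#'   dedup-key copies of earlier reports, in `[0, 1)`.
#' @param aberrant_fraction Fraction of emitted reports whose drug start
#'   dates fall strictly after the event onset date, in `[0, 1)`. Injected
#'   into reports mentioning `target_drug` so the aberrant-record exclusion
#'   removes exactly this many.
#' @param missing_rates Named list of per-field missingness probabilities:
#'   `sex`, `age`, `country`, `event_date`, `start_date`, `end_date`,
#'   `outcome`.
#' @param date_window Length-2 `Date` vector; event dates are uniform over
#'   this window.
#' @param onset_lag List `meanlog`, `sdlog` of the log-normal onset-lag
#'   (days from drug start to event onset), truncated at 0 by rounding.
#' @param demographics List with `male_prob`, `age_mean`, `age_sd`,
#'   `age_range` (clamp), `countries` (tibble `country`, `prob`) and
#'   `outcome_probs` (named over [outcome_levels()], normalised).
#' @param target_drug Catalog drug anchoring aberrant-date injection.
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_reports = 50000,
                             drug_catalog = default_drug_catalog(),
                             event_catalog = default_event_catalog(),
                             association_multipliers = default_association_multipliers(),
                             duplicate_fraction = 0.05,
                             aberrant_fraction = 0.005,
                             missing_rates = list(
                               sex = 0.14, age = 0.30, country = 0,
                               event_date = 0.30, start_date = 0.35,
                               end_date = 0.50, outcome = 0.10),
                             date_window = as.Date(c("2015-01-01", "2019-12-31")),
                             onset_lag = list(meanlog = log(41), sdlog = 1.5),
                             demographics = list(
                               male_prob = 0.55, age_mean = 64, age_sd = 12,
                               age_range = c(1, 95),
                               countries = tibble::tibble(
                                 country = c("US", "DE", "JP", "GB", "CA", "IT", "OTHER"),
                                 prob = c(0.50, 0.10, 0.08, 0.04, 0.03, 0.03, 0.22)),
                               outcome_probs = c(
                                 "death" = 0.07, "life-threatening" = 0.04,
                                 "disability" = 0.01, "hospitalization" = 0.32,
                                 "congenital anomaly" = 0.001,
                                 "required intervention" = 0.001,
                                 "other serious" = 0.558)),
                             target_drug = "carfilzomib",
                             seed = 1L) {
  cfg <- structure(
    list(n_reports = as.integer(n_reports),
         drug_catalog = tibble::as_tibble(drug_catalog),
         event_catalog = tibble::as_tibble(event_catalog),
         association_multipliers = tibble::as_tibble(association_multipliers),
         duplicate_fraction = duplicate_fraction,
         aberrant_fraction = aberrant_fraction,
         missing_rates = missing_rates,
         date_window = date_window,
         onset_lag = onset_lag,
         demographics = demographics,
         target_drug = target_drug,
         seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.na(cfg$n_reports) || cfg$n_reports < 1) {
    stop("n_reports must be a positive integer", call. = FALSE)
  }
  prob01 <- function(p) all(!is.na(p)) && all(p >= 0) && all(p <= 1)
  if (!prob01(cfg$drug_catalog$prob) || !prob01(cfg$event_catalog$prob)) {
    stop("catalog probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(cfg$drug_catalog$name) > 0) {
    stop("drug_catalog names must be unique", call. = FALSE)
  }
  pt_probs <- stats::aggregate(prob ~ pt, data = cfg$event_catalog,
                               FUN = function(x) length(unique(x)))
  if (any(pt_probs$prob > 1)) {
    stop("rows of event_catalog sharing a pt must share its prob",
         call. = FALSE)
  }
  m <- cfg$association_multipliers
  if (nrow(m) > 0) {
    if (any(is.na(m$lambda)) || any(m$lambda <= 0)) {
      stop("association multipliers must be positive", call. = FALSE)
    }
    if (!all(m$drug %in% cfg$drug_catalog$name)) {
      stop("association multiplier references a drug not in the catalog",
           call. = FALSE)
    }
  }
  for (f in c("duplicate_fraction", "aberrant_fraction")) {
    v <- cfg[[f]]
    if (is.na(v) || v < 0 || v >= 1) {
      stop(sprintf("%s must lie in [0, 1)", f), call. = FALSE)
    }
  }
  mr <- cfg$missing_rates
  needed <- c("sex", "age", "country", "event_date", "start_date",
              "end_date", "outcome")
  if (!all(needed %in% names(mr)) || !prob01(unlist(mr[needed]))) {
    stop("missing_rates must name all fields with probabilities in [0, 1]",
         call. = FALSE)
  }
  if (!inherits(cfg$date_window, "Date") || length(cfg$date_window) != 2 ||
      cfg$date_window[2] < cfg$date_window[1]) {
    stop("date_window must be an ordered pair of Dates", call. = FALSE)
  }
  if (cfg$onset_lag$sdlog < 0) {
    stop("onset_lag sdlog must be non-negative", call. = FALSE)
  }
  if (!cfg$target_drug %in% cfg$drug_catalog$name) {
    stop("target_drug must appear in drug_catalog", call. = FALSE)
  }
  # a planted multiplier must not push any per-report PT rate above 1
  rate_cap <- max_pt_rate(cfg)
  if (rate_cap > 1) {
    stop(sprintf(
      "association multipliers push a preferred-term rate to %.3f > 1",
      rate_cap), call. = FALSE)
  }
  invisible(cfg)
}

# largest achievable per-report rate of any PT when every multiplier that
# can touch it is active at once
max_pt_rate <- function(cfg) {
  ec <- cfg$event_catalog
  m <- cfg$association_multipliers
  pts <- unique(ec$pt)
  best <- 0
  for (p in pts) {
    codes <- ec$smq_code[ec$pt == p]
    q <- ec$prob[ec$pt == p][1]
    lam <- m$lambda[m$smq_code %in% codes & m$lambda > 1]
    best <- max(best, q * prod(c(1, lam)))
  }
  best
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> n=%d reports | %d drugs | %d preferred terms | seed %d\n",
    x$n_reports, nrow(x$drug_catalog), length(unique(x$event_catalog$pt)),
    x$seed))
  cat(sprintf("  duplicates %.1f%% | aberrant dates %.1f%% | window %s..%s\n",
              100 * x$duplicate_fraction, 100 * x$aberrant_fraction,
              format(x$date_window[1]), format(x$date_window[2])))
  nm <- x$association_multipliers
  if (nrow(nm) > 0 && any(nm$lambda != 1)) {
    cat(sprintf("  %d planted association multiplier(s)\n",
                sum(nm$lambda != 1)))
  }
  invisible(x)
}
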