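#' Generate a synthetic spontaneous-report cohort
#'
#' Draws `n_reports` spontaneous reports from the stream defined by a
#' [generator_config()]: independent drug mentions, preferred-term rates
#' inflated by the planted (drug, SMQ-category) multipliers for the drugs a
#' report mentions, demographics, calendar event dates, a right-skewed
#' onset lag, field-level missingness, and then two kinds of injected
#' contamination with exactly countable ledgers:
#'
#' * exactly `round(duplicate_fraction * n_reports)` reports are verbatim
#'   dedup-key copies of earlier reports (fresh `report_id`); copies are
#'   drawn only from reports whose dedup-key fields are all present, so
#'   the key-based deduplication removes exactly this many;
#' * exactly `round(aberrant_fraction * n_reports)` reports mentioning the
#'   target drug have every drug start date moved strictly after the event
#'   onset date (both dates left non-missing), so the aberrant-date
#'   exclusion removes exactly this many.
#'
#' Reports with no sampled drug carry the filler entry
#' `"concomitant therapy"`; reports with no sampled reaction carry the
#' filler preferred term `"product dose omission"` (member of no SMQ), so
#' every report has at least one drug and one reaction without disturbing
#' the closed-form cell probabilities of [ground_truth()].
#'
#' @param config A [generator_config()].
#' @return A [report_set()] with attribute `"ledger"` (see
#'   [generator_ledger()]) and attribute `"config"`.
#' @export
generate_reports <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)

  n <- config$n_reports
  n_dup <- as.integer(round(config$duplicate_fraction * n))
  n_ab <- as.integer(round(config$aberrant_fraction * n))
  n_orig <- n - n_dup
  if (n_orig < 1) stop("duplicate_fraction leaves no original reports",
                       call. = FALSE)

  dc <- config$drug_catalog
  ec <- config$event_catalog
  pts <- unique(ec$pt)
  pt_prob <- ec$prob[match(pts, ec$pt)]

  ## drug mention indicators, one column per catalog drug
  present <- matrix(stats::runif(n_orig * nrow(dc)) <
                      rep(dc$prob, each = n_orig),
                    nrow = n_orig)
  colnames(present) <- dc$name

  ## per-report PT rates: baseline inflated by multipliers of mentioned drugs
  rate <- matrix(rep(pt_prob, each = n_orig), nrow = n_orig)
  m <- config$association_multipliers
  for (i in seq_len(nrow(m))) {
    if (m$lambda[i] == 1) next
    rows <- present[, m$drug[i]]
    cols <- which(pts %in% ec$pt[!is.na(ec$smq_code) &
                                   ec$smq_code == m$smq_code[i]])
    if (any(rows) && length(cols) > 0) {
      rate[rows, cols] <- rate[rows, cols] * m$lambda[i]
    }
  }
  has_pt <- matrix(stats::runif(n_orig * length(pts)) < rate, nrow = n_orig)

  ## demographics
  dg <- config$demographics
  sex <- ifelse(stats::runif(n_orig) < dg$male_prob, "male", "female")
  age <- round(pmin(pmax(stats::rnorm(n_orig, dg$age_mean, dg$age_sd),
                         dg$age_range[1]), dg$age_range[2]), 1)
  country <- sample(dg$countries$country, n_orig, replace = TRUE,
                    prob = dg$countries$prob)
  out_p <- dg$outcome_probs / sum(dg$outcome_probs)
  outcome <- sample(names(out_p), n_orig, replace = TRUE, prob = out_p)

  ## dates: event uniform over window, drug start = event - lognormal lag
  span <- as.integer(config$date_window[2] - config$date_window[1])
  event_date <- config$date_window[1] +
    floor(stats::runif(n_orig) * (span + 1))
  reporting_year <- as.integer(format(event_date, "%Y"))
  lag <- round(stats::rlnorm(n_orig, config$onset_lag$meanlog,
                             config$onset_lag$sdlog))
  start_date <- event_date - lag
  duration <- pmax(1, round(stats::rlnorm(n_orig, log(60), 0.7)))
  end_date <- start_date + duration

  ## field-level missingness (before duplication so copies share it)
  mr <- config$missing_rates
  mask <- function(p) stats::runif(n_orig) < p
  sex[mask(mr$sex)] <- NA
  age[mask(mr$age)] <- NA
  country[mask(mr$country)] <- NA
  event_missing <- mask(mr$event_date)
  start_missing <- mask(mr$start_date)
  end_missing <- mask(mr$end_date)
  outcome_missing <- mask(mr$outcome)

  ## aberrant-date injection: drawn from target-drug reports; their event
  ## and start dates are forced observed (the exclusion rule must see both)
  target_col <- present[, config$target_drug]
  candidates <- which(target_col)
  if (length(candidates) < n_ab) {
    stop(sprintf(
      paste0("cannot inject %d aberrant reports: only %d reports mention ",
             "the target drug"),
      n_ab, length(candidates)), call. = FALSE)
  }
  aberrant_idx <- sort(sample(candidates, n_ab))
  if (n_ab > 0) {
    offset <- 1L + stats::rpois(n_ab, 13)
    start_date[aberrant_idx] <- event_date[aberrant_idx] + offset
    end_date[aberrant_idx] <- start_date[aberrant_idx] + duration[aberrant_idx]
    event_missing[aberrant_idx] <- FALSE
    start_missing[aberrant_idx] <- FALSE
    end_missing[aberrant_idx] <- FALSE
  }

  event_date[event_missing] <- NA
  start_date[start_missing] <- NA
  end_date[end_missing] <- NA

  ids <- sprintf("R%07d", seq_len(n))
  orig_ids <- ids[seq_len(n_orig)]

  ## assemble child tables for the originals
  filler_drug <- rowSums(present) == 0
  idx_list <- which(present, arr.ind = TRUE)
  ord <- order(idx_list[, 1], idx_list[, 2])
  drug_rep_idx <- c(idx_list[ord, 1], which(filler_drug))
  drug_names <- c(dc$name[idx_list[ord, 2]],
                  rep("concomitant therapy", sum(filler_drug)))
  dord <- order(drug_rep_idx)
  drug_rep_idx <- drug_rep_idx[dord]
  drug_names <- drug_names[dord]
  drug_tbl <- tibble::tibble(
    report_id = orig_ids[drug_rep_idx],
    drug_seq = stats::ave(drug_rep_idx, drug_rep_idx, FUN = seq_along),
    name = drug_names,
    start_date = start_date[drug_rep_idx],
    end_date = end_date[drug_rep_idx])

  pt_idx <- which(has_pt, arr.ind = TRUE)
  pord <- order(pt_idx[, 1], pt_idx[, 2])
  filler_reac <- rowSums(has_pt) == 0
  reac_rep_idx <- c(pt_idx[pord, 1], which(filler_reac))
  reac_pts <- c(pts[pt_idx[pord, 2]],
                rep("product dose omission", sum(filler_reac)))
  rord <- order(reac_rep_idx)
  reac_tbl <- tibble::tibble(report_id = orig_ids[reac_rep_idx[rord]],
                             pt = reac_pts[rord])

  outc_keep <- !outcome_missing
  outc_tbl <- tibble::tibble(report_id = orig_ids[outc_keep],
                             outcome = outcome[outc_keep])

  demo <- tibble::tibble(
    report_id = orig_ids, sex = sex, age = age, country = country,
    reporting_year = reporting_year, event_date = event_date)

  ## duplicates: verbatim copies of complete-key originals, fresh ids
  duplicate_ids <- character(0)
  if (n_dup > 0) {
    start_by_report <- start_date
    end_by_report <- end_date
    complete_key <- !is.na(sex) & !is.na(age) & !is.na(country) &
      !is.na(event_date) & !is.na(start_by_report) & !is.na(end_by_report) &
      outc_keep
    pool <- which(complete_key)
    if (length(pool) == 0) {
      stop("no complete-key reports available to duplicate", call. = FALSE)
    }
    src <- sample(pool, n_dup, replace = TRUE)
    duplicate_ids <- ids[n_orig + seq_len(n_dup)]
    demo_dup <- demo[src, ]
    demo_dup$report_id <- duplicate_ids
    demo <- dplyr::bind_rows(demo, demo_dup)
    copy_child <- function(tbl) {
      idx <- split(seq_len(nrow(tbl)),
                   factor(tbl$report_id, levels = orig_ids))
      sel <- idx[src]
      out <- tbl[unlist(sel, use.names = FALSE), , drop = FALSE]
      out$report_id <- rep(duplicate_ids, lengths(sel))
      dplyr::bind_rows(tbl, out)
    }
    drug_tbl <- copy_child(drug_tbl)
    reac_tbl <- copy_child(reac_tbl)
    outc_tbl <- copy_child(outc_tbl)
  }

  reports <- report_set(demo, drug_tbl, reac_tbl, outc_tbl)
  attr(reports, "ledger") <- list(
    n_emitted = n,
    n_originals = n_orig,
    n_duplicates = n_dup,
    n_aberrant = n_ab,
    duplicate_ids = duplicate_ids,
    aberrant_ids = orig_ids[aberrant_idx],
    n_target_reports = sum(demo$report_id %in% c(
      orig_ids[target_col], duplicate_ids[
        if (n_dup > 0) target_col[src] else logical(0)])),
    n_drug_rows = nrow(drug_tbl),
    n_reac_rows = nrow(reac_tbl),
    n_outc_rows = nrow(outc_tbl))
  attr(reports, "config") <- config
  reports
}

#' Generator ledger of injected structure
#'
#' @param reports A `report_set` produced by [generate_reports()].
#' @return The ledger list recorded at generation time: emitted counts,
#'   injected duplicate and aberrant report ids, and per-table row counts.
#' @export
generator_ledger <- function(reports) {
  led <- attr(reports, "ledger")
  if (is.null(led)) stop("report_set carries no generator ledger",
                         call. = FALSE)
  led
}

#' Closed-form ground truth implied by a generator configuration
#'
#' For every (catalog drug, SMQ category) pair, computes the exact 2x2 cell
#' probabilities of the generated population — `p11` = P(drug mentioned and
#' at least one category PT reported), etc. — by marginalising analytically
#' over the mention indicators of every other drug whose multipliers touch
#' the category's preferred terms, and the implied information component
#' `expected_ic = log2(p11 / (p_drug * p_event))`, the infinite-sample value
#' of the shrunk IC. With `lambda = 1` the drug and category are independent
#' and `expected_ic` is exactly 0.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per (drug, category): `drug`, `smq_code`,
#'   `lambda`, `p_drug`, `p_event`, `p11`, `p10`, `p01`, `p00`,
#'   `expected_ic`.
#' @export
ground_truth <- function(config) {
  validate_generator_config(config)
  dc <- config$drug_catalog
  ec <- config$event_catalog
  m <- config$association_multipliers
  codes <- sort(unique(ec$smq_code[!is.na(ec$smq_code)]))

  pt_rate_given <- function(pt, drugs_present) {
    q <- ec$prob[ec$pt == pt][1]
    pt_codes <- ec$smq_code[ec$pt == pt]
    rel <- m[m$smq_code %in% pt_codes & m$drug %in% drugs_present, ]
    q * prod(c(1, rel$lambda))
  }

  rows <- list()
  for (j in seq_len(nrow(dc))) {
    drug_j <- dc$name[j]
    p_j <- dc$prob[j]
    for (code in codes) {
      cat_pts <- unique(ec$pt[!is.na(ec$smq_code) & ec$smq_code == code])
      cat_pt_codes <- unique(ec$smq_code[ec$pt %in% cat_pts])
      ## other drugs whose multipliers can touch any PT of this category
      others <- setdiff(unique(m$drug[m$smq_code %in% cat_pt_codes &
                                        m$lambda != 1]), drug_j)
      if (length(others) > 12) {
        stop("too many interacting drugs for exact ground truth",
             call. = FALSE)
      }
      p_cat_given <- function(j_present) {
        total <- 0
        n_o <- length(others)
        for (s in seq_len(2^n_o) - 1L) {
          in_s <- as.logical(bitwAnd(s, 2^(seq_len(n_o) - 1L)) > 0)
          p_s <- prod(c(1, dc$prob[match(others[in_s], dc$name)]),
                      c(1, 1 - dc$prob[match(others[!in_s], dc$name)]))
          drugs <- c(others[in_s], if (j_present) drug_j)
          p_none <- prod(vapply(cat_pts, function(p)
            1 - pt_rate_given(p, drugs), numeric(1)))
          total <- total + p_s * (1 - p_none)
        }
        total
      }
      pc1 <- p_cat_given(TRUE)
      pc0 <- p_cat_given(FALSE)
      p11 <- p_j * pc1
      p10 <- p_j * (1 - pc1)
      p01 <- (1 - p_j) * pc0
      p00 <- (1 - p_j) * (1 - pc0)
      p_event <- p11 + p01
      lam <- m$lambda[m$drug == drug_j & m$smq_code == code]
      rows[[length(rows) + 1]] <- tibble::tibble(
        drug = drug_j, smq_code = code,
        lambda = if (length(lam) == 1) lam else 1,
        p_drug = p_j, p_event = p_event,
        p11 = p11, p10 = p10, p01 = p01, p00 = p00,
        expected_ic = log2(p11 / (p_j * p_event)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate 2x2 tables for one drug-category pair at the contingency level
#'
#' Draws replicate 2x2 contingency tables directly from the multinomial
#' distribution over the four cells implied by [ground_truth()], i.e. the
#' exact sampling distribution of the cleaned cohort's table for that pair.
#' This is the fast path for replicate-heavy calibration and recovery
#' studies; the per-report generator realises the same cell probabilities
#' (cross-checked in the test suite).
#'
#' @param config A [generator_config()] (duplicate and aberrant fractions
#'   are ignored here; pass a clean-stream config).
#' @param drug,smq_code The pair to simulate.
#' @param n_replicates Number of replicate tables.
#' @return Tibble with `n_replicates` rows and columns `a`, `b`, `c`, `d`.
#' @export
simulate_pair_tables <- function(config, drug, smq_code, n_replicates) {
  gt <- ground_truth(config)
  row <- gt[gt$drug == drug & gt$smq_code == smq_code, ]
  if (nrow(row) != 1) stop("pair not found in ground truth", call. = FALSE)
  probs <- c(row$p11, row$p10, row$p01, row$p00)
  draws <- stats::rmultinom(n_replicates, config$n_reports, probs)
  tibble::tibble(a = draws[1, ], b = draws[2, ], c = draws[3, ],
                 d = draws[4, ])
}
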