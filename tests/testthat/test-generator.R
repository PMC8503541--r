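test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_reports = 800, seed = 33)
  r1 <- generate_reports(cfg)
  r2 <- generate_reports(cfg)
  expect_identical(r1$demo, r2$demo)
  expect_identical(r1$drug, r2$drug)
  expect_identical(r1$reac, r2$reac)
  expect_identical(r1$outc, r2$outc)
  r3 <- generate_reports(generator_config(n_reports = 800, seed = 34))
  expect_false(identical(r1$demo, r3$demo))
})

test_that("configuration validation rejects invalid probabilities and multipliers", {
  expect_error(generator_config(n_reports = 0), "positive")
  expect_error(generator_config(duplicate_fraction = 1), "\\[0, 1\\)")
  expect_error(generator_config(
    drug_catalog = tibble::tibble(name = "x", prob = 1.2)), "\\[0, 1\\]")
  expect_error(generator_config(
    association_multipliers = tibble::tibble(
      drug = "carfilzomib", smq_code = 20000004L, lambda = -1)),
    "positive")
  expect_error(generator_config(
    association_multipliers = tibble::tibble(
      drug = "not in catalog", smq_code = 20000004L, lambda = 2)),
    "not in the catalog")
})

test_that("injected duplicate and aberrant counts are exact", {
  cfg <- generator_config(n_reports = 1000, duplicate_fraction = 0.1,
                          aberrant_fraction = 0, seed = 2)
  led <- generator_ledger(generate_reports(cfg))
  expect_identical(led$n_duplicates, 100L)
  expect_length(led$duplicate_ids, 100)

  high_target <- default_drug_catalog()
  high_target$prob[high_target$name == "carfilzomib"] <- 0.30
  cfg2 <- generator_config(n_reports = 2000, duplicate_fraction = 0,
                           aberrant_fraction = 0.05,
                           drug_catalog = high_target, seed = 3)
  rep2 <- generate_reports(cfg2)
  led2 <- generator_ledger(rep2)
  expect_identical(led2$n_aberrant, 100L)
  ## every aberrant report has every drug start strictly after the event
  ab <- filter_reports(rep2, led2$aberrant_ids)
  joined <- merge(ab$drug, ab$demo[, c("report_id", "event_date")],
                  by = "report_id")
  expect_true(all(joined$start_date > joined$event_date))
})

test_that("field-level missingness matches configured rates", {
  cfg <- generator_config(n_reports = 20000, duplicate_fraction = 0,
                          aberrant_fraction = 0, seed = 9)
  rep <- generate_reports(cfg)
  mr <- cfg$missing_rates
  n <- n_reports(rep)
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(is.na(rep$demo$sex)) - mr$sex), tol(mr$sex))
  expect_lt(abs(mean(is.na(rep$demo$age)) - mr$age), tol(mr$age))
  expect_lt(abs(mean(is.na(rep$demo$event_date)) - mr$event_date),
            tol(mr$event_date))
  miss_outc <- 1 - length(unique(rep$outc$report_id)) / n
  expect_lt(abs(miss_outc - mr$outcome), tol(mr$outcome))
})

test_that("null stream yields empirical IC near zero for every pair", {
  cfg <- null_config(n = 50000)
  rep <- generate_reports(cfg)
  smq <- default_smq_map()
  assignment <- assign_categories(rep, smq)
  for (drug in c("carfilzomib", "lenalidomide")) {
    lex <- drug_lexicon(drug)
    is_drug <- match_drug(rep, lex)
    for (code in c(20000004L, 20000081L, 20000147L)) {
      tab <- build_table(rep, is_drug, category_flag(rep, assignment, code))
      ic <- unname(shrunk_ic(tab)["ic"])
      mc_se <- 1 / (log(2) * sqrt(max(tab$a, 1)))
      expect_lt(abs(ic), 3 * mc_se)
    }
  }
})

test_that("a planted multiplier is recovered by the empirical shrunk IC", {
  cfg <- planted_config(lambda = 4, n = 200000)
  rep <- generate_reports(cfg)
  smq <- default_smq_map()
  tab <- build_table(rep, match_drug(rep, carfilzomib_lexicon()),
                     category_flag(rep, assign_categories(rep, smq),
                                   20000004L))
  gt <- ground_truth(cfg)
  expected <- gt$expected_ic[gt$drug == "carfilzomib" &
                               gt$smq_code == 20000004L]
  ic <- unname(shrunk_ic(tab)["ic"])
  mc_se <- 1 / (log(2) * sqrt(tab$a))
  expect_lt(abs(ic - expected), 3 * mc_se)
})

test_that("ground truth has closed-form nulls and matches brute-force frequencies", {
  cfg0 <- null_config(n = 10)
  gt0 <- ground_truth(cfg0)
  expect_true(all(abs(gt0$expected_ic) < 1e-12))
  expect_true(all(abs(gt0$p11 + gt0$p10 + gt0$p01 + gt0$p00 - 1) < 1e-12))
  expect_true(all(gt0$lambda == 1))

  ## rare-event limit: lambda=2 with drug marginal small
  cat1 <- tibble::tibble(name = c("drugx", "other"), prob = c(0.001, 0.05))
  ev1 <- tibble::tibble(pt = c("event a", "filler pt"),
                        prob = c(0.004, 0.05), smq_code = c(20000004L, NA))
  cfg1 <- generator_config(
    n_reports = 10, drug_catalog = cat1, event_catalog = ev1,
    association_multipliers = tibble::tibble(
      drug = "drugx", smq_code = 20000004L, lambda = 2),
    duplicate_fraction = 0, aberrant_fraction = 0,
    target_drug = "drugx", seed = 1)
  gt1 <- ground_truth(cfg1)
  ic1 <- gt1$expected_ic[gt1$drug == "drugx"]
  expect_equal(ic1, 1, tolerance = 0.005)

  ## empirical cell frequencies from a large simulated stream agree with
  ## the analytic cells within 4 binomial SEs
  cfg2 <- planted_config(lambda = 3, n = 200000, seed = 21)
  rep2 <- generate_reports(cfg2)
  gt2 <- ground_truth(cfg2)
  row <- gt2[gt2$drug == "carfilzomib" & gt2$smq_code == 20000004L, ]
  smq <- default_smq_map()
  tab <- build_table(rep2, match_drug(rep2, carfilzomib_lexicon()),
                     category_flag(rep2, assign_categories(rep2, smq),
                                   20000004L))
  n <- n_reports(rep2)
  for (cell in c("p11", "p10", "p01", "p00")) {
    obs <- switch(cell, p11 = tab$a, p10 = tab$b, p01 = tab$c,
                  p00 = tab$d) / n
    p <- row[[cell]]
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("mean empirical IC is non-decreasing in the planted multiplier", {
  set.seed(101)
  means <- vapply(c(1, 2, 4), function(lam) {
    cfg <- planted_config(lambda = lam, n = 50000, seed = 14)
    tabs <- simulate_pair_tables(cfg, "carfilzomib", 20000004L, 200)
    mean(log2((tabs$a + 0.5) /
                (((tabs$a + tabs$b) * (tabs$a + tabs$c) / 50000) + 0.5)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("every report carries at least one drug and one reaction", {
  rep <- generate_reports(generator_config(n_reports = 2000, seed = 8))
  expect_setequal(unique(rep$drug$report_id), rep$demo$report_id)
  expect_setequal(unique(rep$reac$report_id), rep$demo$report_id)
})
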