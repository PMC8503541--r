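test_that("table construction partitions the reports", {
  demo <- tibble::tibble(report_id = sprintf("R%d", 1:4),
                         sex = "male", age = 60, country = "US",
                         reporting_year = 2016L,
                         event_date = as.Date("2016-01-01"))
  empty_drug <- tibble::tibble(report_id = character(0), drug_seq = integer(0),
                               name = character(0),
                               start_date = as.Date(character(0)),
                               end_date = as.Date(character(0)))
  rep <- report_set(demo, empty_drug,
                    tibble::tibble(report_id = character(0), pt = character(0)),
                    tibble::tibble(report_id = character(0),
                                   outcome = character(0)))
  tab <- build_table(rep, c(TRUE, TRUE, FALSE, FALSE),
                     c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), rep(1L, 4))
  expect_error(build_table(filter_reports(rep, rep(FALSE, 4)),
                           logical(0), logical(0)), "empty")
})

test_that("cells equal the independent brute-force recount on generated data", {
  rep <- generate_reports(generator_config(n_reports = 5000, seed = 19))
  smq <- default_smq_map()
  cat_pts <- smq$pt[smq$smq_code == 20000004L]
  manual <- brute_force_cells(rep, c("carfilzomib", "kyprolis"), cat_pts)
  tab <- build_table(rep, match_drug(rep, carfilzomib_lexicon()),
                     category_flag(rep, assign_categories(rep, smq),
                                   20000004L))
  expect_identical(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), manual)
})

test_that("restricting the background first equals a compound predicate", {
  rep <- generate_reports(generator_config(n_reports = 3000, seed = 20))
  smq <- default_smq_map()
  stratum <- !is.na(rep$demo$sex) & rep$demo$sex == "female"
  sub <- filter_reports(rep, stratum)
  tab_sub <- build_table(sub, match_drug(sub, carfilzomib_lexicon()),
                         category_flag(sub, assign_categories(sub, smq),
                                       20000081L))
  is_drug <- match_drug(rep, carfilzomib_lexicon())
  flag <- category_flag(rep, assign_categories(rep, smq), 20000081L)
  tab_full <- contingency_table(sum(stratum & is_drug & flag),
                                sum(stratum & is_drug & !flag),
                                sum(stratum & !is_drug & flag),
                                sum(stratum & !is_drug & !flag))
  expect_identical(c(tab_sub$a, tab_sub$b, tab_sub$c, tab_sub$d),
                   c(tab_full$a, tab_full$b, tab_full$c, tab_full$d))
})

test_that("expected count follows the independence formula", {
  expect_identical(expected_count(contingency_table(0, 0, 50, 50)), 0)
  ## independence: a exactly n_drug*n_event/n_total
  tab <- contingency_table(10, 90, 90, 810)
  expect_equal(expected_count(tab), 10)
  expect_error(expected_count(contingency_table(0, 0, 0, 0)), "empty")
})

test_that("shrunk IC has the shrinkage null and correct sign behaviour", {
  ## a = 0, E = 0: log2(0.5/0.5) = 0
  expect_equal(unname(shrunk_ic(contingency_table(0, 0, 0, 10))["ic"]), 0)
  ## identity case a = E gives exactly 0
  tab <- contingency_table(10, 90, 90, 810)
  expect_equal(unname(shrunk_ic(tab)["ic"]), 0)
  ## sign iff: ic > 0 <=> a > E, over assorted tables
  set.seed(2)
  for (i in 1:50) {
    cells <- stats::rpois(4, c(20, 100, 500, 5000))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    ic <- unname(shrunk_ic(t)["ic"])
    e <- expected_count(t)
    if (cells[1] != e) expect_identical(ic > 0, cells[1] > e)
    ## shrinkage attenuation for over-reported pairs
    if (cells[1] > e && e > 0) expect_lt(ic, log2(cells[1] / e))
  }
})

test_that("interval bounds bracket the point estimates in both methods", {
  tab <- contingency_table(40, 250, 1489, 17121)
  for (m in c("approx", "gamma")) {
    ic <- shrunk_ic(tab, method = m)
    expect_lt(ic["ic025"], ic["ic"])
    expect_lt(ic["ic"], ic["ic975"])
  }
  ror <- ror_estimate(tab)
  expect_lt(ror["ror025"], ror["ror"])
  expect_lt(ror["ror"], ror["ror975"])
})

test_that("reporting odds ratio matches direct arithmetic and symmetry", {
  tab <- contingency_table(10, 90, 100, 9900)
  expect_equal(unname(ror_estimate(tab)["ror"]),
               (10.5 * 9900.5) / (90.5 * 100.5))
  ## symmetric table: ror 1, interval straddles 1
  sym <- ror_estimate(contingency_table(50, 50, 50, 50))
  expect_equal(unname(sym["ror"]), 1)
  expect_lt(sym["ror025"], 1)
  expect_gt(sym["ror975"], 1)
})

test_that("the observed-expected ROR variant equals 2^IC to machine precision", {
  set.seed(3)
  for (i in 1:20) {
    cells <- stats::rpois(4, c(15, 80, 400, 4000))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    oe <- ror_estimate(t, variant = "observed_expected")
    ic <- shrunk_ic(t)
    expect_equal(unname(oe["ror"]), 2^unname(ic["ic"]), tolerance = 1e-12)
    expect_equal(unname(oe["ror025"]), 2^unname(ic["ic025"]),
                 tolerance = 1e-12)
  }
})

test_that("the signal rule is a strict three-part conjunction", {
  expect_true(evaluate_signal(0.85, 1.95, 3370))
  expect_false(evaluate_signal(0.2, 1.5, 2))     # fewer than 3 records
  expect_false(evaluate_signal(0.0, 1.2, 100))   # boundary IC025 = 0
  expect_false(evaluate_signal(0.3, 1.0, 100))   # boundary ROR025 = 1
  expect_true(evaluate_signal(1e-9, 1 + 1e-9, 3))
})

test_that("a single planted association flags exactly that category", {
  cfg <- generator_config(
    n_reports = 100000,
    association_multipliers = tibble::tibble(
      drug = "carfilzomib", smq_code = 20000004L, lambda = 4),
    duplicate_fraction = 0, aberrant_fraction = 0, seed = 23)
  rep <- generate_reports(cfg)
  res <- run_category_analysis(rep, carfilzomib_lexicon(),
                               default_smq_map())
  per_cat <- res[res$category != "total", ]
  expect_true(per_cat$signal[per_cat$smq_code == 20000004L])
  expect_false(any(per_cat$signal[per_cat$smq_code != 20000004L]))
})

test_that("single-year data collapse the time series to the overall estimate", {
  cfg <- planted_config(lambda = 3, n = 20000, seed = 24,
                        date_window = as.Date(c("2017-01-01",
                                                "2017-12-31")))
  rep <- generate_reports(cfg)
  smq <- default_smq_map()
  series <- ic_time_series(rep, carfilzomib_lexicon(), smq, 20000004L)
  expect_identical(nrow(series), 1L)
  overall <- signal_estimate(build_table(
    rep, match_drug(rep, carfilzomib_lexicon()),
    category_flag(rep, assign_categories(rep, smq), 20000004L)))
  expect_equal(series$ic, overall$ic)
  expect_equal(series$ror025, overall$ror025)
})

test_that("a multiplier ramp over years yields increasing cumulative IC", {
  ## simulate a ramp by stacking yearly strata generated at rising lambda
  parts <- lapply(1:3, function(k) {
    cfg <- planted_config(lambda = c(1, 2.5, 6)[k], n = 30000,
                          seed = 30 + k,
                          date_window = as.Date(c(
                            sprintf("%d-01-01", 2014 + k),
                            sprintf("%d-12-31", 2014 + k))))
    rep <- generate_reports(cfg)
    lapply(rep, function(tbl) {
      if ("report_id" %in% names(tbl)) {
        tbl$report_id <- paste0("Y", k, tbl$report_id)
      }
      tbl
    })
  })
  stacked <- report_set(
    dplyr::bind_rows(lapply(parts, `[[`, "demo")),
    dplyr::bind_rows(lapply(parts, `[[`, "drug")),
    dplyr::bind_rows(lapply(parts, `[[`, "reac")),
    dplyr::bind_rows(lapply(parts, `[[`, "outc")))
  series <- ic_time_series(stacked, carfilzomib_lexicon(),
                           default_smq_map(), 20000004L)
  expect_identical(series$year, 2015:2017)
  expect_true(all(diff(series$ic) > 0))
})

test_that("interval width narrows as cumulative evidence accumulates", {
  cfg <- planted_config(lambda = 3, n = 120000, seed = 26)
  rep <- generate_reports(cfg)
  series <- ic_time_series(rep, carfilzomib_lexicon(), default_smq_map(),
                           20000004L)
  widths <- series$ic975 - series$ic025
  expect_true(all(diff(widths[series$usable]) < 0))
})

test_that("an association planted in one sex appears only in that sex's strata", {
  ## plant by generating female reports at lambda 5 and male at 1
  gen_sexed <- function(lam, male_prob, seed, prefix) {
    dg <- list(male_prob = male_prob, age_mean = 64, age_sd = 12,
               age_range = c(1, 95),
               countries = tibble::tibble(country = "US", prob = 1),
               outcome_probs = c("death" = 0.1, "hospitalization" = 0.4,
                                 "other serious" = 0.5))
    cfg <- generator_config(
      n_reports = 60000,
      association_multipliers = tibble::tibble(
        drug = "carfilzomib", smq_code = 20000081L, lambda = lam),
      duplicate_fraction = 0, aberrant_fraction = 0,
      missing_rates = list(sex = 0, age = 0, country = 0,
                           event_date = 0.3, start_date = 0.35,
                           end_date = 0.5, outcome = 0.1),
      demographics = dg, seed = seed)
    rep <- generate_reports(cfg)
    lapply(rep, function(tbl) {
      if ("report_id" %in% names(tbl)) {
        tbl$report_id <- paste0(prefix, tbl$report_id)
      }
      tbl
    })
  }
  males <- gen_sexed(1, 1, 27, "M")
  females <- gen_sexed(5, 0, 28, "F")
  rep <- report_set(dplyr::bind_rows(males$demo, females$demo),
                    dplyr::bind_rows(males$drug, females$drug),
                    dplyr::bind_rows(males$reac, females$reac),
                    dplyr::bind_rows(males$outc, females$outc))
  res <- stratified_analysis(rep, carfilzomib_lexicon(),
                             default_smq_map())
  emb <- res[!is.na(res$smq_code) & res$smq_code == 20000081L, ]
  expect_true(all(emb$signal[emb$sex == "female"]))
  expect_false(any(emb$signal[emb$sex == "male"]))
})

test_that("a one-stratum partition equals the unstratified analysis", {
  cfg <- planted_config(lambda = 3, n = 30000, seed = 29)
  rep <- generate_reports(cfg)
  ## restrict to complete male <65 reports, then compare stratified row
  keep <- !is.na(rep$demo$sex) & rep$demo$sex == "male" &
    !is.na(rep$demo$age) & rep$demo$age < 65
  sub <- filter_reports(rep, keep)
  direct <- run_category_analysis(sub, carfilzomib_lexicon(),
                                  default_smq_map())
  strat <- suppressWarnings(
    stratified_analysis(sub, carfilzomib_lexicon(), default_smq_map()))
  one <- strat[strat$sex == "male" & strat$age_group == "<65", ]
  expect_equal(one$ic, direct$ic)
  expect_equal(one$ror, direct$ror)
})

test_that("an always-true restriction reproduces the main analysis", {
  cfg <- planted_config(lambda = 3, n = 20000, seed = 31)
  rep <- generate_reports(cfg)
  main <- run_category_analysis(rep, carfilzomib_lexicon(),
                                default_smq_map())
  restr <- restricted_background_analysis(
    rep, carfilzomib_lexicon(), default_smq_map(),
    rep(TRUE, n_reports(rep)))
  expect_equal(restr, main)
  expect_error(restricted_background_analysis(
    rep, carfilzomib_lexicon(), default_smq_map(),
    rep(FALSE, n_reports(rep))), "empty")
})

test_that("restriction to the cases' stratum shrinks the background and the IC", {
  ## all carfilzomib reports lie in the "US" stratum; restricting to US
  ## keeps every case but removes background, so IC must decrease
  cfg <- planted_config(lambda = 3, n = 40000, seed = 32)
  rep <- generate_reports(cfg)
  is_drug <- match_drug(rep, carfilzomib_lexicon())
  country <- rep$demo$country
  country[is_drug] <- "US"
  rep$demo$country <- country
  in_us <- !is.na(rep$demo$country) & rep$demo$country == "US"
  smq <- default_smq_map()
  full <- run_category_analysis(rep, carfilzomib_lexicon(), smq)
  restr <- restricted_background_analysis(rep, carfilzomib_lexicon(),
                                          smq, in_us)
  expect_identical(restr$n[1], full$n[1])
  expect_lt(restr$ic[1], full$ic[1])
})

test_that("published marginals reconstruct to the printed estimates", {
  ref <- carfilzomib_reference()
  tab <- reconstruct_table(3370, ref$n_drug, ref$n_total, 2.02)
  expect_equal(expected_count(tab), 1805.0, tolerance = 0.1)
  expect_equal(unname(ror_estimate(tab)["ror"]), 2.02, tolerance = 1e-6)
})
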