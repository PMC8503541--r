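# Hand-built three-report set exercising every field, including a missing
# age and a multi-reaction, multi-drug report.
tiny_reports <- function() {
  demo <- tibble::tibble(
    report_id = c("A1", "A2", "A3"),
    sex = c("male", "female", NA),
    age = c(63, NA, 71.5),
    country = c("US", "DE", "JP"),
    reporting_year = c(2016L, 2017L, 2018L),
    event_date = as.Date(c("2016-04-01", "2017-06-15", NA)))
  drug <- tibble::tibble(
    report_id = c("A1", "A1", "A2", "A3"),
    drug_seq = c(1L, 2L, 1L, 1L),
    name = c("KYPROLIS", "dexamethasone", "bortezomib", "carfilzomib"),
    start_date = as.Date(c("2016-02-20", "2016-02-20", "2017-06-01", NA)),
    end_date = as.Date(c("2016-03-20", NA, "2017-07-01", NA)))
  reac <- tibble::tibble(
    report_id = c("A1", "A1", "A2", "A3"),
    pt = c("cardiac failure", "hypertension", "nausea",
           "pulmonary embolism"))
  outc <- tibble::tibble(
    report_id = c("A1", "A2"),
    outcome = c("hospitalization", "other serious"))
  report_set(demo, drug, reac, outc)
}

# Small null-stream config (no planted association, no contamination).
null_config <- function(n = 5000, seed = 11, ...) {
  generator_config(
    n_reports = n,
    association_multipliers = tibble::tibble(
      drug = character(0), smq_code = integer(0), lambda = numeric(0)),
    duplicate_fraction = 0, aberrant_fraction = 0,
    seed = seed, ...)
}

# Single planted pair: carfilzomib x cardiac failure SMQ at the given
# multiplier, everything else null.
planted_config <- function(lambda, n = 50000, seed = 5, ...) {
  generator_config(
    n_reports = n,
    association_multipliers = tibble::tibble(
      drug = "carfilzomib", smq_code = 20000004L, lambda = lambda),
    duplicate_fraction = 0, aberrant_fraction = 0,
    seed = seed, ...)
}

default_smq_map <- function() smq_map_from_catalog(default_event_catalog())

# Brute-force per-report 2x2 recount, written against the raw tables and
# independent of build_table / match_drug / assign_categories internals.
brute_force_cells <- function(reports, synonyms, category_pts) {
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  ids <- reports$demo$report_id
  drugs_by <- split(norm(reports$drug$name),
                    factor(reports$drug$report_id, levels = ids))
  pts_by <- split(norm(reports$reac$pt),
                  factor(reports$reac$report_id, levels = ids))
  a <- b <- c_ <- d <- 0L
  syn <- norm(synonyms)
  cat_pts <- norm(category_pts)
  for (i in seq_along(ids)) {
    has_drug <- any(drugs_by[[i]] %in% syn)
    has_event <- any(pts_by[[i]] %in% cat_pts)
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}
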