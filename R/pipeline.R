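#' Build and validate a pipeline run configuration
#'
#' A run configuration names exactly one input source — a directory of
#' FAERS-layout tables, or a [generator_config()] for a synthetic cohort —
#' together with the vocabulary inputs and the analysis variants. Every
#' variant defaults to the main-analysis choice (corrected odds-ratio ROR,
#' approximate IC interval, age cutoff 65). Referenced paths are checked
#' here, before any computation.
#'
#' @param input Either a directory path (character) or a
#'   [generator_config()].
#' @param lexicon A [drug_lexicon()] or path to a lexicon file.
#' @param smq_map A `pt`/`smq_code` tibble or path to a mapping file; may
#'   be `NULL` when `input` is a generator config (the map is derived from
#'   its event catalog).
#' @param ror_variant,ic_method,age_cutoff Analysis variants (see
#'   [ror_estimate()], [shrunk_ic()], [stratified_analysis()]).
#' @param stratified Logical, run the sex-by-age stratified analysis.
#' @param background_predicate Optional restriction for a sensitivity
#'   analysis (see [restricted_background_analysis()]).
#' @param seed Integer seed governing any randomness in the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, lexicon = carfilzomib_lexicon(),
                       smq_map = NULL, ror_variant = "odds_ratio",
                       ic_method = "approx", age_cutoff = 65,
                       stratified = FALSE, background_predicate = NULL,
                       seed = 1L) {
  if (is.character(input)) {
    if (!dir.exists(input)) {
      stop(sprintf("input directory '%s' does not exist", input),
           call. = FALSE)
    }
  } else if (!inherits(input, "generator_config")) {
    stop("input must be a directory path or a generator_config",
         call. = FALSE)
  }
  if (is.character(lexicon)) lexicon <- read_drug_lexicon(lexicon)
  if (is.character(smq_map)) smq_map <- read_smq_map(smq_map)
  if (is.null(smq_map)) {
    if (!inherits(input, "generator_config")) {
      stop("smq_map is required when reading an input directory",
           call. = FALSE)
    }
    smq_map <- smq_map_from_catalog(input$event_catalog)
  }
  ror_variant <- match.arg(ror_variant, c("odds_ratio",
                                          "observed_expected"))
  ic_method <- match.arg(ic_method, c("approx", "gamma"))
  structure(list(input = input, lexicon = lexicon, smq_map = smq_map,
                 ror_variant = ror_variant, ic_method = ic_method,
                 age_cutoff = age_cutoff, stratified = stratified,
                 background_predicate = background_predicate,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys: `input_dir` or `generator` (fields of
#' [generator_config()]; catalog defaults fill anything omitted),
#' `lexicon_path`, `smq_map_path`, `ror_variant`, `ic_method`,
#' `age_cutoff`, `stratified`, `seed`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$input_dir) && !is.null(y$generator)) {
    stop("config must name exactly one input source", call. = FALSE)
  }
  input <- if (!is.null(y$input_dir)) {
    y$input_dir
  } else if (!is.null(y$generator)) {
    gen <- y$generator
    if (!is.null(gen$date_window)) gen$date_window <- as.Date(gen$date_window)
    do.call(generator_config, gen)
  } else {
    stop("config must name an input source", call. = FALSE)
  }
  run_config(
    input = input,
    lexicon = if (!is.null(y$lexicon_path)) y$lexicon_path
              else carfilzomib_lexicon(),
    smq_map = y$smq_map_path,
    ror_variant = y$ror_variant %||% "odds_ratio",
    ic_method = y$ic_method %||% "approx",
    age_cutoff = y$age_cutoff %||% 65,
    stratified = isTRUE(y$stratified),
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes ingest (or synthetic generation) -> deduplication ->
#' aberrant-date exclusion -> drug/SMQ mapping -> disproportionality
#' (total, per category, cumulative time trend, optional stratified and
#' restricted-background analyses) -> descriptive summaries, writes every
#' output table plus a run manifest to `out_dir`, and returns the results
#' invisibly. Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return List: `reports` (cleaned set), `cleaning` (combined
#'   `cleaning_report`), `signals`, `time_series`, `stratified` (or
#'   `NULL`), `restricted` (or `NULL`), `characteristics`, `tto`,
#'   `outcomes`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  raw <- if (inherits(config$input, "generator_config")) {
    generate_reports(config$input)
  } else {
    read_reports(config$input)
  }

  dd <- deduplicate(raw)
  ab <- remove_aberrant(dd$reports, config$lexicon)
  cleaning <- combine_cleaning_reports(dd$report, ab$report)
  clean <- ab$reports

  signals <- run_category_analysis(clean, config$lexicon, config$smq_map,
                                   ror_variant = config$ror_variant,
                                   ic_method = config$ic_method)
  time_series <- ic_time_series(clean, config$lexicon, config$smq_map,
                                ror_variant = config$ror_variant,
                                ic_method = config$ic_method)
  stratified <- NULL
  if (isTRUE(config$stratified)) {
    stratified <- stratified_analysis(clean, config$lexicon,
                                      config$smq_map,
                                      age_cutoff = config$age_cutoff,
                                      ror_variant = config$ror_variant,
                                      ic_method = config$ic_method)
  }
  restricted <- NULL
  if (!is.null(config$background_predicate)) {
    restricted <- restricted_background_analysis(
      clean, config$lexicon, config$smq_map, config$background_predicate,
      ror_variant = config$ror_variant, ic_method = config$ic_method)
  }

  ## descriptive surfaces on the target-drug cardiovascular cohort
  is_drug <- match_drug(clean, config$lexicon)
  assignment <- assign_categories(clean, config$smq_map)
  cohort <- filter_reports(clean, is_drug & assignment$is_cardiovascular)
  cohort_assignment <- assign_categories(cohort, config$smq_map)
  characteristics <- characteristics_table(cohort, cohort_assignment,
                                           config$lexicon)
  tto <- tto_summary(time_to_onset(cohort, config$lexicon)$days)
  outcomes <- outcome_profile(cohort)

  manifest <- list(
    config_hash = rlang::hash(list(
      input = config$input, lexicon = config$lexicon,
      smq_map = config$smq_map, ror_variant = config$ror_variant,
      ic_method = config$ic_method, age_cutoff = config$age_cutoff,
      seed = config$seed)),
    seed = config$seed,
    n_input = cleaning$n_input,
    n_duplicates_removed = cleaning$n_duplicates_removed,
    n_aberrant_removed = cleaning$n_aberrant_removed,
    n_retained = cleaning$n_retained,
    n_target_drug = sum(is_drug),
    n_cardiovascular = sum(assignment$is_cardiovascular),
    n_cohort = n_reports(cohort))

  result <- list(reports = clean, cleaning = cleaning, signals = signals,
                 time_series = time_series, stratified = stratified,
                 restricted = restricted,
                 characteristics = characteristics, tto = tto,
                 outcomes = outcomes, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(signals, file.path(out_dir, "signal_table.csv"))
    readr::write_csv(time_series, file.path(out_dir, "time_series.csv"))
    if (!is.null(stratified)) {
      readr::write_csv(stratified, file.path(out_dir, "stratified.csv"))
    }
    if (!is.null(restricted)) {
      readr::write_csv(restricted, file.path(out_dir, "restricted.csv"))
    }
    readr::write_csv(characteristics,
                     file.path(out_dir, "characteristics.csv"))
    readr::write_csv(tto, file.path(out_dir, "time_to_onset.csv"))
    readr::write_csv(outcomes, file.path(out_dir, "outcomes.csv"))
    jsonlite::write_json(unclass(cleaning),
                         file.path(out_dir, "cleaning_report.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  invisible(result)
}
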