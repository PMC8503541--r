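#' Drug lexicon: canonical name plus brand/generic synonyms
#'
#' Matching everywhere in the package is case-insensitive and
#' whitespace-normalized; both brand and generic names identify the target
#' drug.
#'
#' @param canonical Canonical (generic) drug name.
#' @param synonyms Character vector of synonyms (brand and generic names);
#'   the canonical name is included automatically.
#' @return An object of class `drug_lexicon`.
#' @export
drug_lexicon <- function(canonical, synonyms = character(0)) {
  canonical <- normalize_drug_name(canonical)
  synonyms <- unique(c(canonical, normalize_drug_name(synonyms)))
  if (length(synonyms) == 0 || any(!nzchar(synonyms))) {
    stop("lexicon requires a non-empty synonym set", call. = FALSE)
  }
  structure(list(canonical = canonical, synonyms = synonyms),
            class = "drug_lexicon")
}

#' Bundled lexicon for the target proteasome inhibitor
#'
#' @return A [drug_lexicon()] for carfilzomib (generic) and Kyprolis
#'   (brand).
#' @export
carfilzomib_lexicon <- function() {
  drug_lexicon("carfilzomib", c("kyprolis"))
}

#' Read a drug lexicon from a delimited file
#'
#' Expects columns `canonical`, `synonym` (tab- or comma-delimited); all
#' rows must share one canonical name.
#'
#' @param path File path.
#' @return A [drug_lexicon()].
#' @export
read_drug_lexicon <- function(path) {
  tbl <- read_mapping_file(path, c("canonical", "synonym"))
  canon <- unique(tbl$canonical)
  if (length(canon) != 1) {
    stop("lexicon file must define exactly one canonical name",
         call. = FALSE)
  }
  drug_lexicon(canon, tbl$synonym)
}

#' Registry of the eight narrow cardiovascular SMQ categories
#'
#' The eight narrow-scope Standardized MedDRA Queries under which
#' cardiovascular events are grouped, with their SMQ codes. Preferred-term
#' membership is not bundled (MedDRA is licensed); supply it with
#' [read_smq_map()] or derive a synthetic one from an event catalog with
#' [smq_map_from_catalog()].
#'
#' @return Tibble with columns `name`, `smq_code`, `algorithm`.
#' @export
smq_registry <- function() {
  tibble::tibble(
    name = c("cardiac arrhythmias", "cardiac failure", "cardiomyopathy",
             "embolic and thrombotic events", "hypertension",
             "ischemic heart disease", "pulmonary hypertension",
             "torsade de pointes/QT prolongation"),
    smq_code = c(20000049L, 20000004L, 20000150L, 20000081L, 20000147L,
                 20000043L, 20000130L, 20000001L),
    algorithm = "narrow")
}

read_mapping_file <- function(path, cols) {
  if (!file.exists(path)) {
    stop(sprintf("mapping file '%s' does not exist", path), call. = FALSE)
  }
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    stop(sprintf("mapping file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tbl
}

#' Read a preferred-term to SMQ mapping table
#'
#' User-supplied delimited file with columns `pt_name`, `smq_code` (and
#' optionally `algorithm`). Preferred terms are normalized (case-folded,
#' whitespace-collapsed); a PT may map to several categories.
#'
#' @param path File path (`.csv` comma-delimited, otherwise tab).
#' @return Tibble `pt`, `smq_code` with one row per membership.
#' @export
read_smq_map <- function(path) {
  tbl <- read_mapping_file(path, c("pt_name", "smq_code"))
  out <- tibble::tibble(pt = normalize_pt(tbl$pt_name),
                        smq_code = as.integer(tbl$smq_code))
  dplyr::distinct(out)
}

#' Derive a PT-to-SMQ map from a generator event catalog
#'
#' @param event_catalog Tibble `pt`, `smq_code` (as in
#'   [generator_config()]).
#' @return Tibble `pt`, `smq_code` with non-member rows dropped.
#' @export
smq_map_from_catalog <- function(event_catalog) {
  keep <- !is.na(event_catalog$smq_code)
  dplyr::distinct(tibble::tibble(
    pt = normalize_pt(event_catalog$pt[keep]),
    smq_code = as.integer(event_catalog$smq_code[keep])))
}

#' Flag reports mentioning the target drug
#'
#' True for a report iff any of its normalized drug names equals any
#' lexicon synonym (brand or generic).
#'
#' @param reports A [report_set()].
#' @param lexicon A [drug_lexicon()].
#' @return Logical vector along `reports$demo` rows.
#' @export
match_drug <- function(reports, lexicon) {
  stopifnot(inherits(reports, "report_set"))
  if (!inherits(lexicon, "drug_lexicon")) {
    stop("lexicon must be a drug_lexicon", call. = FALSE)
  }
  hit <- normalize_drug_name(reports$drug$name) %in% lexicon$synonyms
  reports$demo$report_id %in% reports$drug$report_id[hit]
}

#' Assign reports to SMQ categories
#'
#' A report belongs to a category iff at least one of its reaction
#' preferred terms is in the category's PT set; it contributes once per
#' category no matter how many of its PTs match, and a report may belong
#' to several categories. Total cardiovascular membership is the union.
#'
#' @param reports A [report_set()].
#' @param smq_map Tibble `pt`, `smq_code` from [read_smq_map()] or
#'   [smq_map_from_catalog()].
#' @return List with `memberships` (tibble `report_id`, `smq_code`, one
#'   row per report-category membership) and `is_cardiovascular` (logical
#'   along `reports$demo` rows).
#' @export
assign_categories <- function(reports, smq_map) {
  stopifnot(inherits(reports, "report_set"))
  reac <- tibble::tibble(report_id = reports$reac$report_id,
                         pt = normalize_pt(reports$reac$pt))
  hits <- dplyr::inner_join(reac, smq_map, by = "pt",
                            relationship = "many-to-many")
  memberships <- dplyr::distinct(hits[, c("report_id", "smq_code")])
  list(memberships = memberships,
       is_cardiovascular = reports$demo$report_id %in%
         memberships$report_id)
}

#' Logical membership vector for one category (or the union)
#'
#' @param reports A [report_set()].
#' @param assignment Result of [assign_categories()].
#' @param smq_code A single SMQ code, or `NULL` for the union of all
#'   categories.
#' @return Logical vector along `reports$demo` rows.
#' @export
category_flag <- function(reports, assignment, smq_code = NULL) {
  mem <- assignment$memberships
  if (!is.null(smq_code)) {
    mem <- mem[mem$smq_code == smq_code, , drop = FALSE]
  }
  reports$demo$report_id %in% mem$report_id
}
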