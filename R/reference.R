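#' Published carfilzomib cardiovascular disproportionality estimates
#'
#' Reference values from a published FAERS (2015-2019) case/non-case
#' analysis of carfilzomib cardiovascular toxicity, bundled so that
#' published rows can be reconstructed and recomputed without access to
#' the 28.5-million-record source database: the cleaned database total,
#' the carfilzomib report total, and per category (plus the total
#' cardiovascular row) the record count and the printed shrunk IC and
#' reporting odds ratio with their lower 95% bounds.
#'
#' @return List with `n_total`, `n_drug`, and `estimates` (tibble:
#'   `category`, `smq_code`, `n`, `ic`, `ic025`, `ror`, `ror025`).
#' @export
carfilzomib_reference <- function() {
  list(
    n_total = 28479963,
    n_drug = 22705,
    estimates = tibble::tribble(
      ~category,                              ~smq_code, ~n,   ~ic,  ~ic025, ~ror, ~ror025,
      "total",                                 NA,        3370, 0.90, 0.85,   2.02, 1.95,
      "cardiac arrhythmias",                   20000049L, 618,  0.47, 0.34,   1.40, 1.29,
      "cardiac failure",                       20000004L, 765,  1.45, 1.33,   2.79, 2.59,
      "cardiomyopathy",                        20000150L, 1301, 1.15, 1.06,   2.29, 2.17,
      "embolic and thrombotic events",         20000081L, 821,  0.71, 0.60,   1.67, 1.55,
      "hypertension",                          20000147L, 254,  0.75, 0.54,   1.69, 1.49,
      "ischemic heart disease",                20000043L, 271,  0.63, 0.43,   1.55, 1.38,
      "pulmonary hypertension",                20000130L, 605,  1.32, 1.19,   2.54, 2.34,
      "torsade de pointes/QT prolongation",    20000001L, 299,  0.52, 0.33,   1.44, 1.29
    ))
}
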