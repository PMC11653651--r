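#' Published per-contrast log2 fold changes (worked example data)
#'
#' The per-miRNA log2 fold changes reported for the feedlot-cattle
#' lameness cohort that this package's generator emulates, shipped as
#' plain TSV under `inst/extdata`. Two tables are available: the
#' pre-treatment (W0) lameness-vs-healthy-control contrasts (columns
#' `contrast, mirna_id, log2fc`, where the contrast is differentially
#' expressed group over HC) and the unrecovered-vs-recovered contrasts
#' per phenotype and week (columns `phenotype, week, mirna_id, log2fc`).
#' They drive the worked example of direction-wise fold-change summaries;
#' feeding a contrast's values into [summarize_directions()] reproduces
#' the cohort's published per-direction averages.
#'
#' @param which `"w0"` or `"recovery"`.
#' @return Tibble of reported fold changes; every row is a DE call, so
#'   [summarize_directions()] applies with `is_de = TRUE`.
#' @export
reported_de_log2fc <- function(which = c("w0", "recovery")) {
  which <- match.arg(which)
  file <- switch(which,
    w0 = "w0_de_log2fc.tsv",
    recovery = "recovery_de_log2fc.tsv"
  )
  path <- system.file("extdata", file, package = "mirlame", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(), log2fc = readr::col_double()
  ), progress = FALSE)
}
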