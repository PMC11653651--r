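#' Read a miRNA count matrix from TSV
#'
#' Expects a tab-separated file whose header is `mirna_id` followed by one
#' column per sample, and whose cells are nonnegative integer read counts.
#' Duplicate miRNA or sample ids and non-integer cells are format errors;
#' a non-integer cell is reported with its (miRNA, sample) coordinates.
#'
#' @param path File path.
#' @return Wide tibble: `mirna_id` plus one integer column per sample.
#' @export
read_counts <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "mirna_id") {
    abort("counts file must start with a 'mirna_id' column")
  }
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf(
      "duplicate sample column: %s",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")
    ))
  }
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, name_repair = "minimal"
  )
  if (anyDuplicated(x$mirna_id)) {
    abort(sprintf(
      "duplicate mirna_id: %s",
      paste(unique(x$mirna_id[duplicated(x$mirna_id)]), collapse = ", ")
    ))
  }
  for (s in samples) {
    bad <- !grepl("^[0-9]+$", x[[s]])
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "non-integer count at miRNA '%s', sample '%s': '%s'",
        x$mirna_id[i], s, x[[s]][i]
      ))
    }
    x[[s]] <- as.integer(x[[s]])
  }
  if (all(colSums(as_expr_matrix(x)) == 0)) {
    abort("count matrix has no nonzero column")
  }
  x
}

#' Write a count (or RPM) matrix as TSV
#'
#' @param x Wide tibble with first column `mirna_id`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path) {
  as_expr_matrix(x) # validates shape and id uniqueness
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

METADATA_COLS <- c(
  "sample_id", "animal_id", "phenotype", "week", "gait_score", "recovery"
)

#' Read and validate a sample metadata table
#'
#' The table must carry the columns `sample_id`, `animal_id`, `phenotype`
#' (HC/DD/FR/TTN/FRDD), `week` (W0/W1/W2), `gait_score` (integer 0-3,
#' empty when not scored) and `recovery` (RE/UNR, empty when undefined).
#' `sample_id` and the pair (`animal_id`, `week`) must be unique. Animals
#' labeled recovered whose gait score did not decrease between their first
#' and last scored week are reported with a warning but kept, so upstream
#' labeling mistakes surface without silently dropping data.
#'
#' @param path File path.
#' @return Validated metadata tibble.
#' @export
read_metadata <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(METADATA_COLS, header)
  if (length(missing) > 0) {
    abort(sprintf(
      "metadata lacks required column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      animal_id = readr::col_character(),
      phenotype = readr::col_character(),
      week = readr::col_character(),
      gait_score = readr::col_integer(),
      recovery = readr::col_character()
    ),
    progress = FALSE
  )
  validate_metadata(x[METADATA_COLS])
}

#' Validate an in-memory metadata tibble
#'
#' Applies the same checks as [read_metadata()]; useful before writing or
#' after constructing metadata programmatically.
#'
#' @param meta Metadata data frame.
#' @return The validated tibble.
#' @export
validate_metadata <- function(meta) {
  meta <- as_tibble(meta)
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf(
      "duplicate sample_id: %s",
      paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")
    ))
  }
  bad <- !is.na(meta$phenotype) & !meta$phenotype %in% PHENOTYPE_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "unknown phenotype value(s): %s",
      paste(unique(meta$phenotype[bad]), collapse = ", ")
    ))
  }
  bad <- !is.na(meta$week) & !meta$week %in% WEEK_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "unknown week value(s): %s", paste(unique(meta$week[bad]), collapse = ", ")
    ))
  }
  gs <- meta$gait_score
  if (any(!is.na(gs) & (gs < 0 | gs > 3))) {
    abort("gait_score must be an integer between 0 and 3")
  }
  bad <- !is.na(meta$recovery) & !meta$recovery %in% RECOVERY_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "unknown recovery value(s): %s",
      paste(unique(meta$recovery[bad]), collapse = ", ")
    ))
  }
  key <- paste(meta$animal_id, meta$week)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "duplicate (animal_id, week): %s",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }

  # Consistency: a recovered label should come with a decreasing gait
  # trajectory; inconsistencies are warnings, never silent edits.
  check <- meta |>
    dplyr::filter(!is.na(.data$gait_score), !is.na(.data$recovery)) |>
    dplyr::arrange(.data$animal_id, match(.data$week, WEEK_LEVELS)) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      recovery = dplyr::first(.data$recovery),
      drop = dplyr::last(.data$gait_score) < dplyr::first(.data$gait_score),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 2, .data$recovery == "RE", !.data$drop)
  if (nrow(check) > 0) {
    warn(sprintf(
      "recovery 'RE' without a decreasing gait trajectory for animal(s): %s",
      paste(check$animal_id, collapse = ", ")
    ))
  }
  meta
}

#' Write a metadata table as TSV
#'
#' Missing gait scores and recovery labels are written as empty fields.
#'
#' @param meta Metadata tibble.
#' @param path Output path.
#' @return `meta`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  readr::write_tsv(meta, path, na = "", progress = FALSE)
  invisible(meta)
}

#' Join-validate a count matrix against sample metadata
#'
#' Errors when the sample id sets differ (naming the offending ids on both
#' sides); otherwise returns the pair with metadata reordered to the count
#' matrix's column order.
#'
#' @param counts Wide count tibble.
#' @param meta Metadata tibble.
#' @return List of class `mirlame_study` with aligned `counts` and
#'   `metadata`.
#' @export
join_validate <- function(counts, meta) {
  m <- as_expr_matrix(counts)
  meta <- validate_metadata(meta)
  extra_counts <- setdiff(colnames(m), meta$sample_id)
  extra_meta <- setdiff(meta$sample_id, colnames(m))
  if (length(extra_counts) > 0 || length(extra_meta) > 0) {
    abort(sprintf(
      "sample id mismatch; only in counts: [%s]; only in metadata: [%s]",
      paste(extra_counts, collapse = ", "),
      paste(extra_meta, collapse = ", ")
    ))
  }
  structure(
    list(
      counts = counts,
      metadata = meta[match(colnames(m), meta$sample_id), ]
    ),
    class = "mirlame_study"
  )
}
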