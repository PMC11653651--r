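# Internal helpers shared across modules.

# Convert a wide count/RPM tibble (first column mirna_id) to a numeric
# matrix with miRNA rownames; validates id uniqueness.
as_expr_matrix <- function(x, what = "counts") {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  if (names(x)[1] != "mirna_id") {
    abort(sprintf("first column of a %s table must be 'mirna_id'", what))
  }
  ids <- as.character(x$mirna_id)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate mirna_id in %s table: %s",
      what, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  samples <- names(x)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf(
      "duplicate sample column in %s table: %s",
      what, paste(unique(samples[duplicated(samples)]), collapse = ", ")
    ))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

# Inverse of as_expr_matrix().
expr_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(mirna_id = rownames(m)), out)
}

# Round half away from zero, the convention used for printed fold-change
# summaries (round() in R rounds half to even).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
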