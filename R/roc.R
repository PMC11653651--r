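#' Empirical AUC for a single marker
#'
#' Computes the area under the ROC curve through its Mann-Whitney
#' identity: the fraction of (class0, class1) pairs in which the class-1
#' value exceeds the class-0 value, counting ties as one half. With
#' `direction = "auto"` (the convention of standard ROC tooling) the
#' orientation is flipped when needed so the reported AUC is at least 0.5,
#' and the chosen orientation is recorded: `">"` means higher values
#' indicate class 1, `"<"` means lower values do.
#'
#' @param values Numeric marker values.
#' @param labels Class labels: logical, 0/1, or a two-level factor (the
#'   second level is class 1).
#' @param direction `"auto"`, `">"`, or `"<"`.
#' @return One-row tibble `auc, direction, n0, n1, band`.
#' @export
roc_auc <- function(values, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  if (is.factor(labels) || is.character(labels)) {
    lev <- unique(as.character(labels))
    if (length(lev) > 2) abort("labels must have exactly two classes")
    labels <- as.character(labels) == sort(lev)[2]
  }
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n0 == 0 || n1 == 0) {
    abort("both classes must be present to compute an AUC")
  }
  r <- rank(values) # midranks: ties contribute 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  dir_used <- ">"
  if (direction == "<" || (direction == "auto" && auc < 0.5)) {
    auc <- 1 - auc
    dir_used <- "<"
  }
  tibble(
    auc = auc, direction = dir_used, n0 = n0, n1 = n1,
    band = classify_band(auc)
  )
}

#' Predictiveness band of an AUC
#'
#' Maps an AUC to the conventional diagnostic bands: excellent
#' `[0.9, 1]`, good `[0.8, 0.9)`, fair `[0.7, 0.8)`, weak `[0.6, 0.7)`,
#' fail `[0.5, 0.6)`, and `below` for `[0, 0.5)`. Intervals are
#' lower-inclusive, so 0.8 is good and 0.9 is excellent. Vectorized.
#'
#' @param auc Numeric AUC value(s) in `[0, 1]`.
#' @return Character vector of band labels.
#' @export
classify_band <- function(auc) {
  if (any(is.na(auc)) || any(auc < 0 | auc > 1)) {
    abort("AUC must lie in [0, 1]")
  }
  as.character(cut(
    auc,
    breaks = c(0, 0.5, 0.6, 0.7, 0.8, 0.9, Inf),
    labels = c("below", "fail", "weak", "fair", "good", "excellent"),
    right = FALSE
  ))
}

roc_table <- function(m, meta_sel, markers, labels01, contrast) {
  absent <- setdiff(markers, rownames(m))
  if (length(absent) > 0) {
    abort(sprintf(
      "marker(s) absent from the RPM matrix: %s",
      paste(absent, collapse = ", ")
    ))
  }
  out <- purrr::map_dfr(markers, function(mk) {
    dplyr::bind_cols(
      tibble(marker = mk, contrast = contrast),
      roc_auc(m[mk, meta_sel$sample_id], labels01)
    )
  })
  class(out) <- c("mirlame_roc", class(out))
  out
}

#' Evaluate markers for differentiating two lameness phenotypes
#'
#' Per-marker ROC/AUC between two phenotypes using the pre-treatment (W0)
#' RPM values, the setting in which candidate diagnostic markers are
#' screened.
#'
#' @param rpm Wide RPM tibble.
#' @param meta Metadata tibble.
#' @param markers Character vector of miRNA ids to evaluate.
#' @param phenotype_a,phenotype_b The two phenotypes (class 0, class 1).
#' @param week Week of the comparison (default `"W0"`).
#' @return Tibble of class `mirlame_roc`: one row per marker with
#'   `marker, contrast, auc, direction, n0, n1, band`.
#' @export
evaluate_differentiation <- function(rpm, meta, markers, phenotype_a,
                                     phenotype_b, week = "W0") {
  m <- as_expr_matrix(rpm, what = "rpm")
  sel <- meta[!is.na(meta$phenotype) &
    meta$phenotype %in% c(phenotype_a, phenotype_b) &
    !is.na(meta$week) & meta$week == week, ]
  sel <- sel[sel$sample_id %in% colnames(m), ]
  labels01 <- sel$phenotype == phenotype_b
  if (sum(labels01) == 0 || sum(!labels01) == 0) {
    abort(sprintf(
      "both phenotypes need samples at %s (%s: %d, %s: %d)",
      week, phenotype_a, sum(!labels01), phenotype_b, sum(labels01)
    ))
  }
  roc_table(m, sel, markers, labels01,
    contrast = sprintf("%s_vs_%s_%s", phenotype_a, phenotype_b, week)
  )
}

#' Evaluate markers for predicting lameness recovery
#'
#' Per-marker ROC/AUC between recovered (RE, class 0) and unrecovered
#' (UNR, class 1) animals of one phenotype, using the RPM values of a
#' given week and the animal-level recovery label.
#'
#' @inheritParams evaluate_differentiation
#' @param phenotype Phenotype stratum.
#' @param week Week whose expression values are used.
#' @return Tibble of class `mirlame_roc`.
#' @export
evaluate_recovery_prediction <- function(rpm, meta, markers, phenotype, week) {
  m <- as_expr_matrix(rpm, what = "rpm")
  sel <- meta[!is.na(meta$phenotype) & meta$phenotype == phenotype &
    !is.na(meta$week) & meta$week == week &
    !is.na(meta$recovery), ]
  sel <- sel[sel$sample_id %in% colnames(m), ]
  if (nrow(sel) == 0) {
    abort(sprintf("no samples for %s at %s", phenotype, week))
  }
  labels01 <- sel$recovery == "UNR"
  if (sum(labels01) == 0 || sum(!labels01) == 0) {
    abort(sprintf(
      "recovery prediction for %s at %s needs both RE and UNR animals",
      phenotype, week
    ))
  }
  roc_table(m, sel, markers, labels01,
    contrast = sprintf("%s_RE_vs_UNR_%s", phenotype, week)
  )
}
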