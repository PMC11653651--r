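#' Delta-delta-Ct relative quantification
#'
#' Normalizes each sample's target Ct to the arithmetic mean Ct of the two
#' reference assays (delta-Ct; equivalent to the geometric mean of their
#' linear quantities), centers on the mean delta-Ct of the calibrator
#' group (delta-delta-Ct), and reports `fold_change = 2^-ddct` assuming
#' perfect doubling per cycle. The geometric mean fold change over the
#' calibrator group is 1 by construction, and any per-sample Ct offset
#' shared by all assays (input amount, plate effects) cancels.
#'
#' @param ct Long Ct tibble `sample_id, assay_id, ct`.
#' @param meta Metadata tibble (provides the grouping column).
#' @param target Target assay id.
#' @param refs Character vector of exactly two reference assay ids.
#' @param reference_group Calibrator group label.
#' @param group_col Metadata column holding the group labels.
#' @return Tibble `sample_id, group, dct, ddct, fold_change`.
#' @export
delta_delta_ct <- function(ct, meta, target, refs, reference_group,
                           group_col = "phenotype") {
  stopifnot(all(c("sample_id", "assay_id", "ct") %in% names(ct)))
  if (length(refs) != 2) abort("exactly two reference assays are required")
  tgt <- ct[ct$assay_id == target, ]
  if (nrow(tgt) == 0) abort(sprintf("target assay '%s' not in Ct table", target))

  ref_ct <- ct[ct$assay_id %in% refs, ] |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_ref = dplyr::n(), ref_ct = mean(.data$ct), .groups = "drop"
    )
  x <- dplyr::left_join(tgt, ref_ct, by = "sample_id")
  bad <- is.na(x$n_ref) | x$n_ref < 2
  if (any(bad)) {
    abort(sprintf(
      "missing reference Ct (%s) for sample(s): %s",
      paste(refs, collapse = ", "),
      paste(x$sample_id[bad], collapse = ", ")
    ))
  }
  groups <- setNames(meta[[group_col]], meta$sample_id)
  if (any(!x$sample_id %in% names(groups))) {
    abort("Ct table contains samples absent from metadata")
  }
  x$group <- unname(groups[x$sample_id])
  in_ref <- !is.na(x$group) & x$group == reference_group
  if (!any(in_ref)) {
    abort(sprintf("reference group '%s' has no samples", reference_group))
  }
  x$dct <- x$ct - x$ref_ct
  calibrator <- mean(x$dct[in_ref])
  x$ddct <- x$dct - calibrator
  tibble(
    sample_id = x$sample_id, group = x$group, dct = x$dct,
    ddct = x$ddct, fold_change = 2^(-x$ddct)
  )
}

#' Direction concordance between sequencing and qPCR fold changes
#'
#' For each target, compares the sign of the sequencing log2 fold change
#' (group B over group A) with the sign of the log2 ratio of the qPCR
#' group geometric-mean fold changes for the same contrast. Targets whose
#' directions agree are concordant.
#'
#' @param seq_de A `mirlame_de` table containing the targets.
#' @param qpcr Named list of [delta_delta_ct()] results (one per target),
#'   or a single result for one target.
#' @param group_a,group_b Contrast groups, matching the sequencing
#'   contrast orientation.
#' @return Tibble `target, seq_log2fc, qpcr_log2_ratio, concordant`.
#' @export
concordance <- function(seq_de, qpcr, group_a, group_b) {
  if (is.data.frame(qpcr)) qpcr <- list(qpcr)
  if (is.null(names(qpcr)) || any(names(qpcr) == "")) {
    abort("qpcr must be a named list: target id -> delta_delta_ct() result")
  }
  purrr::map_dfr(names(qpcr), function(target) {
    hit <- seq_de$log2fc[seq_de$mirna_id == target]
    if (length(hit) == 0) {
      abort(sprintf("target '%s' absent from the sequencing DE table", target))
    }
    rel <- qpcr[[target]]
    mean_log2 <- function(g) {
      sel <- !is.na(rel$group) & rel$group == g
      if (!any(sel)) abort(sprintf("group '%s' absent from qPCR result", g))
      mean(log2(rel$fold_change[sel]))
    }
    ratio <- mean_log2(group_b) - mean_log2(group_a)
    tibble(
      target = target, seq_log2fc = hit[1], qpcr_log2_ratio = ratio,
      concordant = sign(ratio) == sign(hit[1])
    )
  })
}
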