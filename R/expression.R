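#' Reads-per-million normalization
#'
#' Scales each sample column of the count matrix to reads per million
#' mapped reads: `rpm = count / column_total * 1e6`, with the column total
#' of the miRNA count matrix as the mapped-read denominator. Every RPM
#' column therefore sums to exactly one million.
#'
#' @param counts Wide count tibble (`mirna_id` + sample columns).
#' @return Wide RPM tibble of the same shape.
#' @export
rpm_normalize <- function(counts) {
  m <- as_expr_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf(
      "all-zero sample column(s): %s",
      paste(colnames(m)[totals == 0], collapse = ", ")
    ))
  }
  expr_tibble(sweep(m, 2, totals, "/") * 1e6)
}

#' Call expressed miRNAs per sample
#'
#' A miRNA is expressed in a sample when its RPM is strictly greater than
#' the threshold (default 1 RPM); a value exactly at the threshold is not
#' expressed.
#'
#' @param rpm Wide RPM tibble.
#' @param threshold Expression threshold in RPM (>= 0).
#' @return Wide logical tibble of the same shape, with the threshold
#'   attached as attribute `threshold`.
#' @export
call_expressed <- function(rpm, threshold = 1) {
  stopifnot(threshold >= 0)
  m <- as_expr_matrix(rpm, what = "rpm")
  out <- expr_tibble(m > threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Per-group expression prevalence
#'
#' Fraction of samples in each metadata group in which a miRNA is called
#' expressed.
#'
#' @param calls Logical expression-call tibble from [call_expressed()].
#' @param meta Metadata tibble covering the call columns.
#' @param group_col Metadata column defining groups (default `phenotype`).
#' @return Long tibble `mirna_id, group, n_samples, prevalence`.
#' @export
group_prevalence <- function(calls, meta, group_col = "phenotype") {
  m <- as_expr_matrix(calls, what = "calls")
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort("metadata does not cover every call column")
  }
  groups <- meta[[group_col]]
  purrr::map_dfr(unique(groups[!is.na(groups)]), function(g) {
    cols <- which(!is.na(groups) & groups == g)
    tibble(
      mirna_id = rownames(m), group = g, n_samples = length(cols),
      prevalence = rowMeans(m[, cols, drop = FALSE])
    )
  })
}

#' miRNAs expressed at group level
#'
#' A miRNA counts as expressed in a group when it is called expressed in
#' at least `min_prevalence` of the group's samples (default 60%).
#'
#' @inheritParams group_prevalence
#' @param group Group label to evaluate.
#' @param min_prevalence Minimum fraction of expressing samples.
#' @return Character vector of miRNA ids.
#' @export
group_expressed_set <- function(calls, meta, group, min_prevalence = 0.6,
                                group_col = "phenotype") {
  prev <- group_prevalence(calls, meta, group_col)
  hit <- prev[prev$group == group, ]
  if (nrow(hit) == 0) {
    abort(sprintf("group '%s' has no samples", group))
  }
  hit$mirna_id[hit$prevalence >= min_prevalence]
}

#' Detect phenotype-specific miRNAs
#'
#' A miRNA is specific to a phenotype when it is expressed in at least
#' `min_prevalence` of that phenotype's samples while its prevalence in
#' every other phenotype stays at or below `max_other_prevalence`
#' (default 0: expressed in no sample of any other group, the strictest
#' reading of "not in other groups"). When permissive parameters let a
#' miRNA qualify for several groups it is assigned to the group with the
#' highest prevalence (ties: excluded), so the output sets are disjoint.
#'
#' @inheritParams group_prevalence
#' @param min_prevalence Minimum prevalence in the claiming group.
#' @param max_other_prevalence Maximum prevalence tolerated elsewhere.
#' @return Tibble `group, mirna_id, prevalence`, one row per specific
#'   miRNA.
#' @export
detect_phenotype_specific <- function(calls, meta, min_prevalence = 0.6,
                                      max_other_prevalence = 0,
                                      group_col = "phenotype") {
  prev <- group_prevalence(calls, meta, group_col) |>
    tidyr::pivot_wider(
      id_cols = "mirna_id", names_from = "group", values_from = "prevalence"
    )
  groups <- setdiff(names(prev), "mirna_id")
  if (length(groups) < 2) {
    abort("phenotype-specific detection needs at least two groups")
  }
  P <- as.matrix(prev[groups])
  qual <- sapply(seq_along(groups), function(gi) {
    P[, gi] >= min_prevalence &
      apply(P[, -gi, drop = FALSE], 1, max) <= max_other_prevalence
  })
  qual <- matrix(qual, ncol = length(groups))
  empty <- tibble(
    group = character(0), mirna_id = character(0), prevalence = numeric(0)
  )
  if (!any(qual)) {
    return(empty)
  }
  purrr::map_dfr(which(rowSums(qual) > 0), function(i) {
    cand <- which(qual[i, ])
    if (length(cand) > 1) {
      best <- cand[P[i, cand] == max(P[i, cand])]
      if (length(best) > 1) {
        return(tibble(
          group = character(0), mirna_id = character(0),
          prevalence = numeric(0)
        ))
      }
      cand <- best
    }
    tibble(
      group = groups[cand], mirna_id = prev$mirna_id[i],
      prevalence = P[i, cand]
    )
  })
}

#' Detect time-point-specific miRNAs within a phenotype
#'
#' Within one phenotype, a miRNA is specific to a week when it is
#' group-expressed (the same >= `min_prevalence` prevalence rule, applied
#' to that phenotype-week stratum) at that week and at no other sampled
#' week.
#'
#' @inheritParams group_prevalence
#' @param phenotype Phenotype to analyze.
#' @param min_prevalence Prevalence rule for group-level expression.
#' @return Tibble `week, mirna_id, prevalence`.
#' @export
detect_timepoint_specific <- function(calls, meta, phenotype,
                                      min_prevalence = 0.6,
                                      group_col = "phenotype") {
  meta_ph <- meta[!is.na(meta[[group_col]]) & meta[[group_col]] == phenotype, ]
  weeks <- intersect(WEEK_LEVELS, unique(meta_ph$week))
  if (length(weeks) < 2) {
    abort(sprintf("phenotype '%s' needs samples at >= 2 weeks", phenotype))
  }
  m <- as_expr_matrix(calls, what = "calls")
  prev_by_week <- sapply(weeks, function(w) {
    cols <- intersect(colnames(m), meta_ph$sample_id[meta_ph$week == w])
    rowMeans(m[, cols, drop = FALSE])
  })
  expressed <- prev_by_week >= min_prevalence
  specific <- expressed & rowSums(expressed) == 1
  purrr::map_dfr(weeks, function(w) {
    hit <- which(specific[, w])
    tibble(
      week = w, mirna_id = rownames(m)[hit],
      prevalence = prev_by_week[hit, w]
    )
  })
}

#' Top expressed miRNAs and their share of the reads
#'
#' Ranks miRNAs by mean RPM across samples and reports which ids make up
#' the top `k` together with the fraction of all reads they carry.
#'
#' @param rpm Wide RPM tibble.
#' @param k Number of top miRNAs (default 10).
#' @return List with `mirna_ids` (sorted by mean RPM, descending) and
#'   `share` in `[0, 1]`.
#' @export
top_expressed_share <- function(rpm, k = 10) {
  m <- as_expr_matrix(rpm, what = "rpm")
  if (k > nrow(m)) abort("k exceeds the number of miRNAs")
  means <- rowMeans(m)
  ord <- order(means, decreasing = TRUE)
  top <- ord[seq_len(k)]
  list(
    mirna_ids = rownames(m)[top],
    share = sum(means[top]) / sum(means)
  )
}
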