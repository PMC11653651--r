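#' Median-of-ratios size factors
#'
#' Per-sample scaling factors for sequencing depth and composition,
#' computed as the median ratio of each sample's counts to the per-miRNA
#' geometric mean across samples, restricted to miRNAs with nonzero counts
#' in every sample. When no such reference miRNA exists the
#' `"poscounts"`-style fallback computes each miRNA's geometric mean over
#' its positive counts only and takes medians over positive ratios, which
#' keeps sparse matrices usable. Factors are rescaled to geometric mean 1.
#'
#' @param counts Wide count tibble.
#' @param method `"ratio"` (strict; errors when no miRNA is positive in
#'   all samples), `"poscounts"`, or `"auto"` (ratio with poscounts
#'   fallback, the default).
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts, method = c("auto", "ratio", "poscounts")) {
  method <- match.arg(method)
  m <- as_expr_matrix(counts)
  logm <- log(m)
  loggeo <- rowMeans(logm)
  usable <- is.finite(loggeo)
  if (method != "poscounts" && !any(usable)) {
    if (method == "ratio") {
      abort("no miRNA has nonzero counts in every sample; see method = 'poscounts'")
    }
    method <- "poscounts"
  }
  if (method == "poscounts") {
    ratios <- lapply(seq_len(nrow(m)), function(i) {
      pos <- m[i, ] > 0
      if (sum(pos) == 0) {
        return(rep(NA_real_, ncol(m)))
      }
      geo <- exp(mean(logm[i, pos]))
      out <- rep(NA_real_, ncol(m))
      out[pos] <- m[i, pos] / geo
      out
    })
    s <- apply(do.call(rbind, ratios), 2, median, na.rm = TRUE)
  } else {
    ratios <- m[usable, , drop = FALSE] / exp(loggeo[usable])
    s <- apply(ratios, 2, median)
  }
  if (any(!is.finite(s) | s <= 0)) {
    abort("size factor estimation failed (zero or non-finite factor)")
  }
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(m))
}

#' Method-of-moments negative-binomial dispersion with trend shrinkage
#'
#' For each miRNA the within-group mean/variance of size-factor-normalized
#' counts give a raw dispersion estimate solving `Var = mu + alpha * mu^2`
#' (clamped at 0), which is then shrunk halfway toward a mean-dispersion
#' trend `alpha(mu) = a0 + a1 / mu` fitted across miRNAs. This is a
#' deliberately simple stand-in for full maximum-likelihood dispersion
#' machinery: adequate for Wald calibration on simulated data.
#'
#' @param counts Wide count tibble.
#' @param size_factors Named size factors as from
#'   [estimate_size_factors()].
#' @param groups Character/factor vector of group labels, one per sample
#'   column.
#' @return Named per-miRNA dispersion vector (alpha >= 0).
#' @export
estimate_dispersion <- function(counts, size_factors, groups) {
  m <- as_expr_matrix(counts)
  stopifnot(length(groups) == ncol(m))
  k <- sweep(m, 2, size_factors[colnames(m)], "/")
  groups <- as.character(groups)
  glev <- unique(groups)
  if (any(table(groups) < 2)) abort("every group needs >= 2 samples")

  num <- 0
  den <- 0
  for (g in glev) {
    kg <- k[, groups == g, drop = FALSE]
    ng <- ncol(kg)
    mg <- rowMeans(kg)
    vg <- apply(kg, 1, var)
    num <- num + (ng - 1) * (vg - mg)
    den <- den + (ng - 1) * mg^2
  }
  mu <- rowMeans(k)
  raw <- ifelse(den > 0, pmax(0, num / den), 0)

  ok <- mu > 0 & is.finite(raw)
  trend <- rep(0, nrow(m))
  if (sum(ok) >= 10) {
    fit <- lm(raw[ok] ~ I(1 / mu[ok]))
    trend[ok] <- pmax(0, coef(fit)[1] + coef(fit)[2] / mu[ok])
  } else {
    trend[ok] <- median(raw[ok])
  }
  alpha <- pmax(0, 0.5 * raw + 0.5 * trend)
  setNames(alpha, rownames(m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validated front for
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per miRNA, the closed-form two-level NB model with log link and
#' size-factor offsets: the group means of size-factor-normalized counts
#' are the fitted group abundances, `log2fc = log2(q_b / q_a)` (group B
#' over group A), and the Wald standard error comes from the delta method
#' with `Var(count) = mu + alpha * mu^2` at the estimated dispersion.
#' Two-sided normal p-values are BH-adjusted, and a miRNA is flagged
#' differentially expressed when `|log2fc| > lfc_threshold` and
#' `fdr < fdr_threshold` (the defaults are the conventional |log2FC| > 1,
#' FDR < 0.05 call rule). miRNAs with zero counts across both groups are
#' excluded from testing; a zero mean in one group is replaced by a
#' pseudo-mean of 0.5 normalized counts so fold changes stay finite.
#'
#' @param counts Wide count tibble.
#' @param meta Metadata covering the tested samples.
#' @param group_a,group_b Labels of the reference (A) and test (B) group.
#' @param group_col Metadata column holding the labels (default
#'   `phenotype`; use `"week"` for interval contrasts or `"recovery"` for
#'   recovery contrasts).
#' @param week Optional week filter applied before testing.
#' @param lfc_threshold,fdr_threshold Call-rule thresholds.
#' @param size_factors,dispersion Optional precomputed values; estimated
#'   from the selected samples when omitted.
#' @return Tibble of class `mirlame_de`: `mirna_id, base_mean, log2fc,
#'   lfc_se, stat, pvalue, padj, is_de`, with the contrast stored in
#'   attribute `contrast`.
#' @export
nb_wald_test <- function(counts, meta, group_a, group_b,
                         group_col = "phenotype", week = NULL,
                         lfc_threshold = 1, fdr_threshold = 0.05,
                         size_factors = NULL, dispersion = NULL) {
  if (!is.null(week)) {
    meta <- meta[!is.na(meta$week) & meta$week %in% week, ]
  }
  lab <- meta[[group_col]]
  ids_a <- meta$sample_id[!is.na(lab) & lab == group_a]
  ids_b <- meta$sample_id[!is.na(lab) & lab == group_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort(sprintf(
      "both groups need >= 2 samples (%s: %d, %s: %d)",
      group_a, length(ids_a), group_b, length(ids_b)
    ))
  }
  m <- as_expr_matrix(counts)
  missing <- setdiff(c(ids_a, ids_b), colnames(m))
  if (length(missing) > 0) {
    abort(sprintf(
      "samples absent from counts: %s", paste(missing, collapse = ", ")
    ))
  }
  sel <- m[, c(ids_a, ids_b), drop = FALSE]
  keep <- rowSums(sel) > 0
  sel <- sel[keep, , drop = FALSE]
  grp <- rep(c("A", "B"), c(length(ids_a), length(ids_b)))

  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(expr_tibble(sel))
  }
  s <- size_factors[colnames(sel)]
  k <- sweep(sel, 2, s, "/")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(expr_tibble(sel), size_factors, grp)
  }
  alpha <- rep_len(dispersion, nrow(sel))
  if (!is.null(names(dispersion))) alpha <- dispersion[rownames(sel)]

  ka <- k[, grp == "A", drop = FALSE]
  kb <- k[, grp == "B", drop = FALSE]
  qa <- rowMeans(ka)
  qb <- rowMeans(kb)
  qa_adj <- ifelse(qa > 0, qa, 0.5)
  qb_adj <- ifelse(qb > 0, qb, 0.5)
  log2fc <- log2(qb_adj / qa_adj)

  # Var(mean of k_j) with k_j = y_j / s_j, Var(y_j) = mu_j + alpha mu_j^2,
  # mu_j = s_j q  =>  Var(k_j) = q / s_j + alpha q^2.
  var_q <- function(q, cols) {
    sj <- s[colnames(cols)]
    sapply(seq_along(q), function(i) {
      sum(q[i] / sj + alpha[i] * q[i]^2) / ncol(cols)^2
    })
  }
  va <- var_q(qa_adj, ka)
  vb <- var_q(qb_adj, kb)
  ln2sq <- log(2)^2
  se <- sqrt(va / (qa_adj^2 * ln2sq) + vb / (qb_adj^2 * ln2sq))
  stat <- log2fc / se
  pvalue <- 2 * pnorm(-abs(stat))
  padj <- adjust_bh(pvalue)

  out <- tibble(
    mirna_id = rownames(sel),
    base_mean = unname(rowMeans(k)),
    log2fc = unname(log2fc),
    lfc_se = unname(se),
    stat = unname(stat),
    pvalue = unname(pvalue),
    padj = unname(padj),
    is_de = unname(abs(log2fc) > lfc_threshold & padj < fdr_threshold)
  )
  class(out) <- c("mirlame_de", class(out))
  attr(out, "contrast") <- c(group_a = group_a, group_b = group_b)
  attr(out, "thresholds") <- c(lfc = lfc_threshold, fdr = fdr_threshold)
  out
}

#' Direction-wise summary of differentially expressed miRNAs
#'
#' Splits the DE calls of a contrast by fold-change sign and reports the
#' count and mean log2 fold change per direction, rounded half away from
#' zero to `precision` decimals (the convention used for printed summary
#' values). Means are `NA` when a direction is empty.
#'
#' @param de A `mirlame_de` table (or any tibble with `log2fc` and
#'   `is_de`).
#' @param precision Decimal places for the reported means.
#' @return One-row tibble `n_up, n_down, mean_log2fc_up,
#'   mean_log2fc_down`.
#' @export
summarize_directions <- function(de, precision = 2) {
  hits <- de$log2fc[de$is_de]
  up <- hits[hits > 0]
  down <- hits[hits < 0]
  tibble(
    n_up = length(up),
    n_down = length(down),
    mean_log2fc_up = if (length(up) > 0) round_half_away(mean(up), precision) else NA_real_,
    mean_log2fc_down = if (length(down) > 0) round_half_away(mean(down), precision) else NA_real_
  )
}

#' Write a differential-expression table as TSV
#'
#' Uses the conventional column names of NB Wald output (`baseMean`,
#' `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`) for
#' interoperability with downstream tooling.
#'
#' @param de A `mirlame_de` table.
#' @param path Output path.
#' @return `de`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- tibble(
    mirna_id = de$mirna_id, baseMean = de$base_mean,
    log2FoldChange = de$log2fc, lfcSE = de$lfc_se, stat = de$stat,
    pvalue = de$pvalue, padj = de$padj, is_de = de$is_de
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(de)
}

#' @export
glance.mirlame_de <- function(x, ...) {
  contrast <- attr(x, "contrast")
  tibble(
    group_a = unname(contrast["group_a"]),
    group_b = unname(contrast["group_b"]),
    n_tested = nrow(x),
    n_de = sum(x$is_de),
    n_up = sum(x$is_de & x$log2fc > 0),
    n_down = sum(x$is_de & x$log2fc < 0)
  )
}

#' @export
tidy.mirlame_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirlame_de")
  attr(out, "contrast") <- NULL
  attr(out, "thresholds") <- NULL
  out
}
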