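#' Pipeline configuration
#'
#' Collects every analysis threshold in one validated object so a run is
#' self-documenting: the RPM expression threshold, the prevalence rule for
#' group-level expression, the |log2FC| and FDR call rule, the fuzzy
#' C-means settings and the signature membership threshold.
#'
#' @param rpm_expressed Expression threshold in RPM (strict `>`).
#' @param min_prevalence Group-level expression prevalence rule.
#' @param max_other_prevalence Tolerated prevalence outside the claiming
#'   group for phenotype-specific calls.
#' @param lfc_threshold,fdr_threshold Differential-expression call rule.
#' @param membership_threshold Signature membership rule (strict `>`).
#' @param fcm_c,fcm_m,fcm_tol,fcm_max_iter,fcm_seed Fuzzy C-means
#'   settings; `fcm_c = 9` defaults to one cluster per nominal temporal
#'   pattern category.
#' @return List of class `mirlame_pipeline_config`.
#' @export
pipeline_config <- function(rpm_expressed = 1, min_prevalence = 0.6,
                            max_other_prevalence = 0,
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            membership_threshold = 0.7,
                            fcm_c = 9, fcm_m = 2, fcm_tol = 1e-6,
                            fcm_max_iter = 1000, fcm_seed = 1) {
  stopifnot(
    rpm_expressed >= 0,
    min_prevalence >= 0, min_prevalence <= 1,
    max_other_prevalence >= 0, max_other_prevalence <= 1,
    lfc_threshold >= 0, fdr_threshold > 0, fdr_threshold <= 1,
    membership_threshold >= 0, membership_threshold <= 1,
    fcm_c >= 2, fcm_m > 1, fcm_tol > 0, fcm_max_iter >= 1
  )
  structure(
    as.list(environment()),
    class = "mirlame_pipeline_config"
  )
}

log_step <- function(fmt, ...) message(sprintf(fmt, ...))

prepare_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Pre-treatment (W0) analysis
#'
#' Runs the cross-sectional stage on the W0 samples: RPM normalization,
#' expression calling, phenotype-specific detection, one differential
#' expression table per lameness-vs-control and pairwise contrast, and
#' direction-wise summaries. All tables are written as TSV under
#' `out_dir` and returned invisibly.
#'
#' @param counts Wide count tibble.
#' @param meta Metadata tibble.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param contrasts Optional list of `c(group_a, group_b)` pairs;
#'   defaults to every lameness phenotype vs HC (when present) plus all
#'   pairwise lameness contrasts.
#' @return Invisible list: `rpm`, `calls`, `specific`, `de` (named list of
#'   `mirlame_de`), `summaries`.
#' @export
run_w0_analysis <- function(counts, meta, out_dir,
                            config = pipeline_config(), contrasts = NULL) {
  stopifnot(inherits(config, "mirlame_pipeline_config"))
  study <- join_validate(counts, meta)
  meta_w0 <- study$metadata[study$metadata$week == "W0", ]
  if (length(unique(meta_w0$phenotype)) < 2) {
    abort("W0 analysis needs samples from at least two phenotypes")
  }
  prepare_out_dir(out_dir)
  m <- as_expr_matrix(study$counts)
  counts_w0 <- expr_tibble(m[, meta_w0$sample_id, drop = FALSE])

  log_step("W0 analysis: %d miRNAs x %d samples", nrow(m), nrow(meta_w0))
  rpm <- rpm_normalize(counts_w0)
  calls <- call_expressed(rpm, config$rpm_expressed)
  log_step(
    "expression calls at RPM > %g: %d miRNAs expressed somewhere",
    config$rpm_expressed, sum(rowSums(as_expr_matrix(calls, "calls")) > 0)
  )
  write_counts(rpm, file.path(out_dir, "rpm_W0.tsv"))

  specific <- detect_phenotype_specific(
    calls, meta_w0,
    min_prevalence = config$min_prevalence,
    max_other_prevalence = config$max_other_prevalence
  )
  rpm_m <- as_expr_matrix(rpm, "rpm")
  group_rpm <- function(id, g, f) {
    f(rpm_m[id, meta_w0$sample_id[meta_w0$phenotype == g]])
  }
  specific$mean_rpm <- purrr::map2_dbl(
    specific$mirna_id, specific$group, group_rpm, f = mean
  )
  specific$sd_rpm <- purrr::map2_dbl(
    specific$mirna_id, specific$group, group_rpm, f = sd
  )
  log_step("phenotype-specific miRNAs: %d", nrow(specific))
  readr::write_tsv(
    specific, file.path(out_dir, "specific_mirnas.tsv"), progress = FALSE
  )

  phenos <- intersect(PHENOTYPE_LEVELS, unique(meta_w0$phenotype))
  if (is.null(contrasts)) {
    lame <- setdiff(phenos, "HC")
    contrasts <- list()
    if ("HC" %in% phenos) {
      contrasts <- lapply(lame, function(g) c("HC", g))
    }
    if (length(lame) >= 2) {
      pairs <- utils::combn(lame, 2, simplify = FALSE)
      contrasts <- c(contrasts, pairs)
    }
  }

  de <- list()
  summaries <- list()
  for (cc in contrasts) {
    nm <- sprintf("%s_vs_%s", cc[2], cc[1])
    tab <- nb_wald_test(
      counts_w0, meta_w0, cc[1], cc[2],
      lfc_threshold = config$lfc_threshold,
      fdr_threshold = config$fdr_threshold
    )
    de[[nm]] <- tab
    summaries[[nm]] <- dplyr::bind_cols(
      tibble(contrast = nm), summarize_directions(tab)
    )
    log_step(
      "contrast %s: %d tested, %d DE (%d up, %d down)",
      nm, nrow(tab), sum(tab$is_de),
      sum(tab$is_de & tab$log2fc > 0), sum(tab$is_de & tab$log2fc < 0)
    )
    write_de_table(tab, file.path(out_dir, sprintf("de_%s.tsv", nm)))
  }
  summaries <- dplyr::bind_rows(summaries)
  readr::write_tsv(
    summaries, file.path(out_dir, "de_direction_summaries.tsv"),
    progress = FALSE
  )

  invisible(list(
    rpm = rpm, calls = calls, specific = specific, de = de,
    summaries = summaries
  ))
}

#' Longitudinal temporal-pattern analysis
#'
#' For each (phenotype, recovery) stratum with complete W0-W2 coverage:
#' average-RPM time courses, standardized profiles, fuzzy C-means
#' clustering with signature selection, interval trend calls and the
#' nine-category pattern table. Additionally one RE-vs-UNR differential
#' expression table per phenotype and week. Tables are written as TSV
#' under `out_dir`.
#'
#' @inheritParams run_w0_analysis
#' @return Invisible list: `clusters` (named list of `mirlame_fcm`),
#'   `signatures`, `patterns`, `recovery_de` (named lists per stratum /
#'   phenotype-week).
#' @export
run_longitudinal_analysis <- function(counts, meta, out_dir,
                                      config = pipeline_config()) {
  stopifnot(inherits(config, "mirlame_pipeline_config"))
  study <- join_validate(counts, meta)
  meta <- study$metadata
  prepare_out_dir(out_dir)
  rpm <- rpm_normalize(study$counts)
  weeks <- c("W0", "W1", "W2")

  strata <- meta |>
    dplyr::filter(!is.na(.data$recovery)) |>
    dplyr::distinct(.data$phenotype, .data$recovery)
  if (nrow(strata) == 0) abort("no samples carry a recovery label")

  clusters <- list()
  signatures <- list()
  patterns <- list()
  for (i in seq_len(nrow(strata))) {
    ph <- strata$phenotype[i]
    rec <- strata$recovery[i]
    nm <- paste0(ph, rec)
    have <- meta$week[meta$phenotype == ph & !is.na(meta$recovery) &
      meta$recovery == rec]
    if (!all(weeks %in% have)) {
      abort(sprintf("stratum %s lacks one of %s", nm, paste(weeks, collapse = "/")))
    }
    tc <- build_timecourse(rpm, meta, ph, rec, weeks)
    z <- standardize_profiles(tc)
    n_prof <- nrow(z)
    c_used <- min(config$fcm_c, n_prof - 1)
    if (c_used < config$fcm_c) {
      warn(sprintf(
        "stratum %s: only %d clusterable profiles, reducing c to %d",
        nm, n_prof, c_used
      ))
    }
    model <- fcm_cluster(
      z,
      c = c_used, m = config$fcm_m, tol = config$fcm_tol,
      max_iter = config$fcm_max_iter, seed = config$fcm_seed
    )
    sig <- select_signatures(model, config$membership_threshold)
    pat <- trend_patterns(
      study$counts, meta, ph, rec, weeks,
      lfc_threshold = config$lfc_threshold,
      fdr_threshold = config$fdr_threshold
    )
    clusters[[nm]] <- model
    signatures[[nm]] <- sig
    patterns[[nm]] <- pat
    log_step(
      "stratum %s: %d profiles, %d signatures, %d pattern rows",
      nm, n_prof, nrow(sig), nrow(pat)
    )
    assignment <- fcm_assignments(model) |>
      dplyr::mutate(
        is_signature = .data$membership > config$membership_threshold
      )
    readr::write_tsv(
      assignment, file.path(out_dir, sprintf("clusters_%s.tsv", nm)),
      progress = FALSE
    )
    readr::write_tsv(
      pat, file.path(out_dir, sprintf("patterns_%s.tsv", nm)),
      progress = FALSE
    )
  }

  recovery_de <- list()
  for (ph in unique(strata$phenotype)) {
    for (w in weeks) {
      sub <- meta[meta$phenotype == ph & meta$week == w &
        !is.na(meta$recovery), ]
      if (length(unique(sub$recovery)) < 2 ||
        any(table(sub$recovery) < 2)) {
        warn(sprintf("skipping RE-vs-UNR for %s at %s: single class", ph, w))
        next
      }
      nm <- sprintf("%s_UNR_vs_RE_%s", ph, w)
      tab <- nb_wald_test(
        study$counts, sub, "RE", "UNR",
        group_col = "recovery",
        lfc_threshold = config$lfc_threshold,
        fdr_threshold = config$fdr_threshold
      )
      recovery_de[[nm]] <- tab
      log_step("contrast %s: %d tested, %d DE", nm, nrow(tab), sum(tab$is_de))
      write_de_table(tab, file.path(out_dir, sprintf("de_%s.tsv", nm)))
    }
  }

  invisible(list(
    clusters = clusters, signatures = signatures, patterns = patterns,
    recovery_de = recovery_de
  ))
}

#' Marker ROC/AUC analysis
#'
#' Evaluates candidate markers for pairwise phenotype differentiation at
#' W0 and, where recovery labels exist, for recovery prediction per week.
#' By default the markers for each pairwise contrast are that contrast's
#' DE miRNAs (computed on the fly); single-class contrasts are skipped
#' with a warning.
#'
#' @inheritParams run_w0_analysis
#' @param markers Optional fixed character vector of markers; when `NULL`
#'   each contrast uses its own DE set.
#' @return Invisible list: `differentiation`, `recovery` (named lists of
#'   `mirlame_roc` tables).
#' @export
run_marker_analysis <- function(counts, meta, out_dir,
                                config = pipeline_config(), markers = NULL) {
  stopifnot(inherits(config, "mirlame_pipeline_config"))
  study <- join_validate(counts, meta)
  meta <- study$metadata
  prepare_out_dir(out_dir)
  rpm <- rpm_normalize(study$counts)

  meta_w0 <- meta[meta$week == "W0", ]
  lame <- intersect(setdiff(PHENOTYPE_LEVELS, "HC"), unique(meta_w0$phenotype))
  differentiation <- list()
  if (length(lame) >= 2) {
    for (pair in utils::combn(lame, 2, simplify = FALSE)) {
      nm <- sprintf("%s_vs_%s", pair[1], pair[2])
      mk <- markers
      if (is.null(mk)) {
        de <- nb_wald_test(
          study$counts, meta_w0, pair[1], pair[2],
          lfc_threshold = config$lfc_threshold,
          fdr_threshold = config$fdr_threshold
        )
        mk <- de$mirna_id[de$is_de]
      }
      if (length(mk) == 0) {
        warn(sprintf("no markers for contrast %s; skipped", nm))
        next
      }
      tab <- evaluate_differentiation(rpm, meta, mk, pair[1], pair[2])
      differentiation[[nm]] <- tab
      log_step("markers %s: %d evaluated", nm, nrow(tab))
      readr::write_tsv(
        tab, file.path(out_dir, sprintf("markers_%s.tsv", nm)),
        progress = FALSE
      )
    }
  }

  recovery <- list()
  with_rec <- unique(meta$phenotype[!is.na(meta$recovery)])
  for (ph in with_rec) {
    for (w in intersect(WEEK_LEVELS, unique(meta$week))) {
      sub <- meta[meta$phenotype == ph & meta$week == w &
        !is.na(meta$recovery), ]
      if (length(unique(sub$recovery)) < 2) {
        warn(sprintf(
          "skipping recovery markers for %s at %s: single class", ph, w
        ))
        next
      }
      mk <- markers
      if (is.null(mk)) {
        de <- nb_wald_test(
          study$counts, sub, "RE", "UNR",
          group_col = "recovery",
          lfc_threshold = config$lfc_threshold,
          fdr_threshold = config$fdr_threshold
        )
        mk <- de$mirna_id[de$is_de]
      }
      if (length(mk) == 0) next
      nm <- sprintf("%s_recovery_%s", ph, w)
      tab <- evaluate_recovery_prediction(rpm, meta, mk, ph, w)
      recovery[[nm]] <- tab
      log_step("recovery markers %s: %d evaluated", nm, nrow(tab))
      readr::write_tsv(
        tab, file.path(out_dir, sprintf("markers_%s.tsv", nm)),
        progress = FALSE
      )
    }
  }

  invisible(list(differentiation = differentiation, recovery = recovery))
}
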