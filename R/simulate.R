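#' Baseline relative-abundance profile dominated by a few miRNAs
#'
#' Whole-blood small RNA libraries are strongly skewed: a handful of
#' erythroid miRNAs (miR-486 and the let-7 family in cattle) take most of
#' the reads. This helper builds a deterministic relative-abundance vector
#' in which the ten most abundant miRNAs hold `top10_share` of the mass
#' (geometric decay within the head) and the remaining mass decays
#' geometrically across the tail, so the least abundant miRNAs sit near the
#' 1 RPM expression threshold.
#'
#' @param n_mirnas Number of miRNAs (>= 11).
#' @param top10_share Fraction of total reads carried by the top ten
#'   miRNAs (default 0.85).
#' @param head_decay,tail_decay Geometric decay ratios inside the head and
#'   tail blocks.
#' @return Named numeric vector summing to 1.
#' @export
default_baseline_profile <- function(n_mirnas, top10_share = 0.85,
                                     head_decay = 0.55, tail_decay = 0.975) {
  stopifnot(n_mirnas >= 11, top10_share > 0, top10_share < 1)
  head_w <- head_decay^(0:9)
  head_w <- head_w / sum(head_w) * top10_share
  n_tail <- n_mirnas - 10
  tail_w <- tail_decay^(seq_len(n_tail) - 1)
  tail_w <- tail_w / sum(tail_w) * (1 - top10_share)
  p <- c(head_w, tail_w)
  names(p) <- sprintf("sim-miR-%03d", seq_len(n_mirnas))
  p
}

#' Configuration for the synthetic study generator
#'
#' Bundles and validates every knob of the negative-binomial count
#' generator. The defaults reproduce the design of the cross-sectional
#' pre-treatment arm of the cattle-lameness study the package models:
#' five phenotype groups (HC n=12, DD n=24, FR n=40, TTN n=13, FRDD n=17,
#' 106 samples), a library depth of ~6.7 million reads per sample (the
#' study's 709 million reads over 106 libraries), and a baseline abundance
#' profile whose top ten miRNAs carry 85% of the reads.
#'
#' @param n_mirnas Number of simulated miRNAs.
#' @param group_sizes Named integer vector, phenotype -> number of animals.
#' @param weeks Ordered character vector of sampling weeks; `"W0"` for a
#'   cross-sectional study, `c("W0","W1","W2")` for longitudinal cohorts.
#' @param library_size_mean Mean sequencing depth per sample (reads).
#' @param library_size_cv Coefficient of variation of the log-normal
#'   library-size distribution (0 = constant depth).
#' @param dispersion Negative-binomial dispersion alpha, with
#'   Var = mu + alpha * mu^2; 0 gives Poisson counts.
#' @param baseline_profile Per-miRNA expected relative abundance summing to
#'   1; defaults to [default_baseline_profile()].
#' @param planted_de Tibble `mirna_id, group, log2fc`: the named group's
#'   mean is multiplied by `2^log2fc`, so any contrast of that group
#'   against an unmodified group has the stated true log2 fold change.
#' @param planted_specific Tibble `mirna_id, group, target_rpm`: the miRNA
#'   is expressed at `target_rpm` reads-per-million in the named group and
#'   has zero mean everywhere else.
#' @param planted_patterns Tibble `mirna_id, phenotype, recovery, pattern`
#'   with `pattern` one of the nine `U/N/D` interval categories (for
#'   [simulate_recovery_cohort()]).
#' @param pattern_log2fc Absolute per-interval log2 fold change applied for
#'   `U`/`D` pattern letters (default 2; `N` letters shift nothing).
#' @param recovery_fraction Fraction of animals per phenotype whose gait
#'   trajectory improves (label RE).
#' @param seed Integer seed; identical configurations give byte-identical
#'   simulated studies.
#' @return A list of class `mirlame_config`.
#' @export
simulation_config <- function(n_mirnas = 300,
                              group_sizes = c(HC = 12, DD = 24, FR = 40, TTN = 13, FRDD = 17),
                              weeks = "W0",
                              library_size_mean = 6.7e6,
                              library_size_cv = 0.3,
                              dispersion = 0.2,
                              baseline_profile = NULL,
                              planted_de = NULL,
                              planted_specific = NULL,
                              planted_patterns = NULL,
                              pattern_log2fc = 2,
                              recovery_fraction = 0.5,
                              seed = 1L) {
  if (is.null(baseline_profile)) {
    baseline_profile <- default_baseline_profile(n_mirnas)
  }
  if (length(baseline_profile) != n_mirnas) {
    abort("baseline_profile length must equal n_mirnas")
  }
  if (is.null(names(baseline_profile))) {
    names(baseline_profile) <- sprintf("sim-miR-%03d", seq_len(n_mirnas))
  }
  if (abs(sum(baseline_profile) - 1) > 1e-9) {
    abort("baseline_profile must sum to 1 (within 1e-9)")
  }
  if (any(baseline_profile < 0)) abort("baseline_profile must be nonnegative")
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes))) {
    abort("group_sizes must be uniquely named (phenotype -> n)")
  }
  bad_groups <- !names(group_sizes) %in% PHENOTYPE_LEVELS
  if (any(bad_groups)) {
    abort(sprintf(
      "unknown phenotype in group_sizes: %s",
      paste(names(group_sizes)[bad_groups], collapse = ", ")
    ))
  }
  if (any(group_sizes < 2)) abort("every group must have >= 2 animals")
  if (!all(weeks %in% WEEK_LEVELS)) abort("weeks must be drawn from W0/W1/W2")
  stopifnot(
    library_size_mean > 0, library_size_cv >= 0, dispersion >= 0,
    pattern_log2fc >= 0, recovery_fraction >= 0, recovery_fraction <= 1
  )

  ids <- names(baseline_profile)
  planted_de <- validate_planted(planted_de, c("mirna_id", "group", "log2fc"), ids)
  planted_specific <- validate_planted(
    planted_specific, c("mirna_id", "group", "target_rpm"), ids
  )
  planted_patterns <- validate_planted(
    planted_patterns, c("mirna_id", "phenotype", "recovery", "pattern"), ids
  )
  if (nrow(planted_patterns) > 0) {
    if (!all(planted_patterns$pattern %in% PATTERN_LEVELS)) {
      abort("planted pattern strings must be one of the nine U/N/D categories")
    }
    if (!all(planted_patterns$recovery %in% RECOVERY_LEVELS)) {
      abort("planted pattern recovery must be RE or UNR")
    }
  }
  for (tab in list(planted_de, planted_specific)) {
    if (nrow(tab) > 0 && !all(tab$group %in% names(group_sizes))) {
      abort("planted effect names a group absent from group_sizes")
    }
  }

  structure(
    list(
      n_mirnas = n_mirnas, group_sizes = group_sizes, weeks = weeks,
      library_size_mean = library_size_mean, library_size_cv = library_size_cv,
      dispersion = dispersion, baseline_profile = baseline_profile,
      planted_de = planted_de, planted_specific = planted_specific,
      planted_patterns = planted_patterns, pattern_log2fc = pattern_log2fc,
      recovery_fraction = recovery_fraction, seed = as.integer(seed)
    ),
    class = "mirlame_config"
  )
}

validate_planted <- function(x, cols, mirna_ids) {
  if (is.null(x)) {
    x <- as_tibble(setNames(rep(list(character(0)), length(cols)), cols))
    numish <- intersect(cols, c("log2fc", "target_rpm"))
    for (cc in numish) x[[cc]] <- numeric(0)
    return(x)
  }
  x <- as_tibble(x)
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("planted table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  absent <- setdiff(x$mirna_id, mirna_ids)
  if (length(absent) > 0) {
    abort(sprintf(
      "planted miRNA id(s) absent from baseline profile: %s",
      paste(absent, collapse = ", ")
    ))
  }
  x[cols]
}

# Per-group expected relative abundance after planting specific and DE
# effects. Columns = groups.
group_abundance <- function(config) {
  p <- config$baseline_profile
  groups <- names(config$group_sizes)
  A <- matrix(p, nrow = length(p), ncol = length(groups),
    dimnames = list(names(p), groups)
  )
  spec <- config$planted_specific
  if (nrow(spec) > 0) {
    for (i in seq_len(nrow(spec))) {
      A[spec$mirna_id[i], ] <- 0
      A[spec$mirna_id[i], spec$group[i]] <- spec$target_rpm[i] / 1e6
    }
  }
  de <- config$planted_de
  if (nrow(de) > 0) {
    for (i in seq_len(nrow(de))) {
      A[de$mirna_id[i], de$group[i]] <-
        A[de$mirna_id[i], de$group[i]] * 2^de$log2fc[i]
    }
  }
  A
}

draw_library_sizes <- function(n, mean, cv) {
  if (cv == 0) {
    return(rep(mean, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion > 0) {
    rnbinom(n, mu = mu, size = 1 / dispersion)
  } else {
    rpois(n, lambda = mu)
  }
}

#' Simulate a cross-sectional miRNA count study with planted truth
#'
#' Draws negative-binomial read counts for every (miRNA, sample) cell with
#' log-normal per-sample library sizes, per-group mean shifts for planted
#' differential effects, and zeroed off-group means for planted
#' phenotype-specific miRNAs. Everything planted is recorded verbatim in
#' the returned truth tables, and an identical configuration (including
#' seed) reproduces the study exactly.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mirlame_sim` with elements `counts` (wide
#'   tibble, `mirna_id` + one column per sample), `metadata` (one row per
#'   sample), `truth_de`, `truth_specific`, `truth_patterns`,
#'   `truth_recovery`, and the `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "mirlame_config"))
  withr::local_seed(config$seed)

  groups <- names(config$group_sizes)
  meta <- purrr::map_dfr(groups, function(g) {
    n <- config$group_sizes[[g]]
    animal <- sprintf("%s%03d", g, seq_len(n))
    tidyr::expand_grid(animal_id = animal, week = config$weeks) |>
      dplyr::mutate(
        sample_id = paste(.data$animal_id, .data$week, sep = "_"),
        phenotype = g
      )
  })
  meta <- meta |>
    dplyr::mutate(
      gait_score = ifelse(.data$phenotype == "HC", 0L,
        sample(1:3, nrow(meta), replace = TRUE)
      ),
      recovery = NA_character_
    ) |>
    dplyr::select(
      "sample_id", "animal_id", "phenotype", "week",
      "gait_score", "recovery"
    )

  counts <- draw_count_matrix(config, meta$phenotype, meta$sample_id)

  new_sim(
    counts = counts, metadata = meta, config = config,
    truth_de = config$planted_de, truth_specific = config$planted_specific,
    truth_patterns = config$planted_patterns,
    truth_recovery = tibble(
      animal_id = character(0), phenotype = character(0),
      recovery = character(0)
    )
  )
}

# Draw the count matrix for samples with given per-sample group column of
# the abundance matrix; multiplier optionally scales each sample's mean
# vector (used for temporal patterns).
draw_count_matrix <- function(config, sample_group, sample_ids,
                              multiplier = NULL) {
  A <- group_abundance(config)
  n_samples <- length(sample_group)
  lib <- draw_library_sizes(
    n_samples, config$library_size_mean, config$library_size_cv
  )
  cm <- matrix(0L, nrow = config$n_mirnas, ncol = n_samples,
    dimnames = list(rownames(A), sample_ids)
  )
  for (j in seq_len(n_samples)) {
    mu <- lib[j] * A[, sample_group[j]]
    if (!is.null(multiplier)) mu <- mu * multiplier[, j]
    cm[, j] <- draw_counts(mu, config$dispersion)
  }
  expr_tibble(cm)
}

new_sim <- function(counts, metadata, config, truth_de, truth_specific,
                    truth_patterns, truth_recovery) {
  structure(
    list(
      counts = counts, metadata = metadata,
      truth_de = truth_de, truth_specific = truth_specific,
      truth_patterns = truth_patterns, truth_recovery = truth_recovery,
      config = config
    ),
    class = "mirlame_sim"
  )
}

#' Simulate a longitudinal recovery cohort
#'
#' Each animal contributes one sample at W0, W1 and W2. A configured
#' fraction of animals per phenotype recovers: their gait scores strictly
#' decrease from diagnosis to W2, while unrecovered animals' scores never
#' decrease. The recovery label in the truth table follows the gait rule
#' (final score below the initial score means recovered). Planted temporal
#' patterns move the group mean of a miRNA by `pattern_log2fc` log2 units
#' per `U`/`D` interval within the targeted (phenotype, recovery) stratum.
#'
#' @inheritParams simulate_counts
#' @return A `mirlame_sim` list; `truth_recovery` has one row per animal.
#' @export
simulate_recovery_cohort <- function(config) {
  stopifnot(inherits(config, "mirlame_config"))
  if (length(config$weeks) < 3) {
    abort("a recovery cohort needs the three weeks W0, W1, W2")
  }
  weeks <- config$weeks[1:3]
  withr::local_seed(config$seed)

  groups <- names(config$group_sizes)
  animals <- purrr::map_dfr(groups, function(g) {
    n <- config$group_sizes[[g]]
    n_re <- round(config$recovery_fraction * n)
    tibble(
      animal_id = sprintf("%s%03d", g, seq_len(n)),
      phenotype = g,
      recovery = rep(c("RE", "UNR"), c(n_re, n - n_re))
    )
  })

  # Gait trajectories: lame at diagnosis (score 2-3); recovered animals
  # drop one point per week (floored at 0), unrecovered stay or worsen.
  g0 <- sample(2:3, nrow(animals), replace = TRUE)
  worsen <- rbinom(nrow(animals), 1, 0.3)
  traj <- purrr::pmap(
    list(g0, animals$recovery, worsen),
    function(g, rec, w) {
      if (rec == "RE") c(g, g - 1L, max(g - 2L, 0L)) else c(g, g, min(g + w, 3L))
    }
  )

  meta <- tidyr::expand_grid(
    animals, week = weeks
  ) |>
    dplyr::mutate(
      sample_id = paste(.data$animal_id, .data$week, sep = "_"),
      gait_score = purrr::map2_int(
        rep(seq_len(nrow(animals)), each = length(weeks)),
        rep(seq_along(weeks), nrow(animals)),
        function(a, w) as.integer(traj[[a]][w])
      )
    ) |>
    dplyr::select(
      "sample_id", "animal_id", "phenotype", "week",
      "gait_score", "recovery"
    )

  # Per-sample mean multiplier implementing the planted U/N/D patterns.
  mult <- matrix(1, nrow = config$n_mirnas, ncol = nrow(meta),
    dimnames = list(names(config$baseline_profile), meta$sample_id)
  )
  pats <- config$planted_patterns
  if (nrow(pats) > 0) {
    step <- c(U = config$pattern_log2fc, N = 0, D = -config$pattern_log2fc)
    rec_by_animal <- setNames(animals$recovery, animals$animal_id)
    for (i in seq_len(nrow(pats))) {
      letters2 <- strsplit(pats$pattern[i], "-", fixed = TRUE)[[1]]
      lfc_by_week <- cumsum(c(0, step[letters2[1]], step[letters2[2]]))
      in_stratum <- meta$phenotype == pats$phenotype[i] &
        rec_by_animal[meta$animal_id] == pats$recovery[i]
      w_idx <- match(meta$week, weeks)
      mult[pats$mirna_id[i], in_stratum] <-
        2^lfc_by_week[w_idx[in_stratum]]
    }
  }

  counts <- draw_count_matrix(config, meta$phenotype, meta$sample_id, mult)

  new_sim(
    counts = counts, metadata = meta, config = config,
    truth_de = config$planted_de, truth_specific = config$planted_specific,
    truth_patterns = config$planted_patterns,
    truth_recovery = animals
  )
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates threshold-cycle (Ct) values for target assays and two
#' reference assays across the configured groups. Each sample carries a
#' shared technical offset (input amount, efficiency) that affects every
#' assay equally and therefore cancels in delta-Ct; planted fold changes
#' lower the target Ct by `log2(fold_change)` cycles in their group
#' relative to the calibrator group. Reference assays have fold change 1
#' everywhere.
#'
#' @param config A [simulation_config()]; its `group_sizes` set the number
#'   of biological replicates per group and its `seed` the randomness.
#' @param planted_fold_changes Tibble `target, group, fold_change` with
#'   fold changes relative to `reference_group`; omitted (target, group)
#'   pairs default to 1.
#' @param refs Character vector of exactly two reference assay ids.
#' @param reference_group Calibrator group (default the first group).
#' @param noise_sd Gaussian Ct measurement noise, in cycles.
#' @param sample_ct_sd Spread of the per-sample technical offset, cycles.
#' @param base_ct,ref_ct Baseline cycle numbers of target and reference
#'   assays.
#' @return List of class `mirlame_ct_sim`: `ct` (long tibble `sample_id,
#'   assay_id, ct`), `metadata`, `truth_fold_changes`, `refs`,
#'   `reference_group`.
#' @export
simulate_ct_table <- function(config, planted_fold_changes,
                              refs = c("bta-miR-93", "bta-miR-16b"),
                              reference_group = names(config$group_sizes)[1],
                              noise_sd = 0.2, sample_ct_sd = 0.5,
                              base_ct = 25, ref_ct = 20) {
  stopifnot(inherits(config, "mirlame_config"))
  if (length(refs) != 2 || anyDuplicated(refs) || any(is.na(refs))) {
    abort("exactly two distinct reference assay ids are required")
  }
  fc <- as_tibble(planted_fold_changes)
  need <- c("target", "group", "fold_change")
  if (!all(need %in% names(fc))) {
    abort("planted_fold_changes needs columns target, group, fold_change")
  }
  if (!all(fc$group %in% names(config$group_sizes))) {
    abort("planted fold change names a group absent from group_sizes")
  }
  if (any(fc$fold_change <= 0)) abort("fold changes must be positive")
  targets <- unique(fc$target)
  if (any(refs %in% targets)) {
    abort("reference assays cannot also be targets")
  }
  if (!reference_group %in% names(config$group_sizes)) {
    abort(sprintf("reference group '%s' not in group_sizes", reference_group))
  }

  withr::local_seed(config$seed)
  groups <- names(config$group_sizes)
  meta <- purrr::map_dfr(groups, function(g) {
    tibble(
      animal_id = sprintf("%s%03d", g, seq_len(config$group_sizes[[g]])),
      phenotype = g
    )
  }) |>
    dplyr::mutate(
      sample_id = paste0(.data$animal_id, "_W0"), week = "W0",
      gait_score = NA_integer_, recovery = NA_character_
    ) |>
    dplyr::select(
      "sample_id", "animal_id", "phenotype", "week",
      "gait_score", "recovery"
    )

  offset <- rnorm(nrow(meta), 0, sample_ct_sd)
  fc_lookup <- function(target, group) {
    hit <- fc$fold_change[fc$target == target & fc$group == group]
    if (length(hit) == 0) 1 else hit[1]
  }
  assays <- c(targets, refs)
  ct <- tidyr::expand_grid(
    sample_idx = seq_len(nrow(meta)), assay_id = assays
  ) |>
    dplyr::mutate(
      sample_id = meta$sample_id[.data$sample_idx],
      group = meta$phenotype[.data$sample_idx],
      is_ref = .data$assay_id %in% refs,
      ct = ifelse(.data$is_ref, ref_ct, base_ct) +
        offset[.data$sample_idx] -
        ifelse(.data$is_ref, 0,
          log2(purrr::map2_dbl(.data$assay_id, .data$group, fc_lookup))
        ) +
        rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    dplyr::select("sample_id", "assay_id", "ct")

  structure(
    list(
      ct = ct, metadata = meta, truth_fold_changes = fc[need],
      refs = refs, reference_group = reference_group, config = config
    ),
    class = "mirlame_ct_sim"
  )
}
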