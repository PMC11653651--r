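#' Average-RPM time course for one (phenotype, recovery) stratum
#'
#' For every miRNA, the arithmetic mean RPM over the stratum's samples at
#' each week, in week order. Every requested week must have at least one
#' sample.
#'
#' @param rpm Wide RPM tibble.
#' @param meta Metadata tibble.
#' @param phenotype Phenotype label of the stratum.
#' @param recovery Optional recovery label (`"RE"`/`"UNR"`); omit to pool
#'   both.
#' @param weeks Ordered weeks of the time course.
#' @return Wide tibble `mirna_id` + one column per week.
#' @export
build_timecourse <- function(rpm, meta, phenotype, recovery = NULL,
                             weeks = c("W0", "W1", "W2")) {
  m <- as_expr_matrix(rpm, what = "rpm")
  keep <- !is.na(meta$phenotype) & meta$phenotype == phenotype
  if (!is.null(recovery)) {
    keep <- keep & !is.na(meta$recovery) & meta$recovery == recovery
  }
  sub <- meta[keep, ]
  profiles <- sapply(weeks, function(w) {
    ids <- intersect(colnames(m), sub$sample_id[sub$week == w])
    if (length(ids) == 0) {
      abort(sprintf(
        "no samples for phenotype %s%s at week %s",
        phenotype,
        if (is.null(recovery)) "" else paste0("/", recovery), w
      ))
    }
    rowMeans(m[, ids, drop = FALSE])
  })
  expr_tibble(profiles)
}

#' Standardize time-course profiles
#'
#' Centers each profile to mean 0 and scales it to standard deviation 1
#' across time points, the usual pre-step before fuzzy C-means clustering
#' so clusters group by shape rather than abundance. Constant
#' (zero-variance) profiles carry no shape information and are excluded;
#' their ids are attached as attribute `excluded`.
#'
#' @param tc Wide time-course tibble from [build_timecourse()].
#' @return Standardized wide tibble with attribute `excluded`.
#' @export
standardize_profiles <- function(tc) {
  m <- as_expr_matrix(tc, what = "time course")
  mu <- rowMeans(m)
  # population (1/T) standard deviation: profiles are complete series,
  # not samples from a longer one
  sdev <- sqrt(rowMeans((m - mu)^2))
  keep <- sdev > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  out <- expr_tibble(z)
  attr(out, "excluded") <- rownames(m)[!keep]
  out
}

#' Fuzzy C-means clustering of expression profiles
#'
#' Classic fuzzy C-means: memberships are initialized from the seeded
#' uniform generator (rows normalized to 1), then centroid updates
#' `v_k = sum(u^m x) / sum(u^m)` alternate with membership updates
#' `u_ik = 1 / sum_l (d_ik^2 / d_il^2)^(1/(m-1))` until the largest
#' centroid shift drops below `tol` or `max_iter` is reached. A profile
#' coinciding with one or more centroids gets its membership split evenly
#' among the coinciding clusters. The weighted within-cluster objective
#' `sum u^m d^2` is nonincreasing across iterations.
#'
#' @param x Wide profile tibble (`mirna_id` + numeric columns), typically
#'   from [standardize_profiles()], or a numeric matrix with rownames.
#' @param c Number of clusters (2 <= c < number of profiles).
#' @param m Fuzzifier (> 1, default 2).
#' @param tol Convergence tolerance on the centroid shift.
#' @param max_iter Iteration cap.
#' @param seed Seed for the membership initialization.
#' @param init_memberships Optional N x c initial membership matrix (rows
#'   summing to 1), overriding the seeded initialization.
#' @return Object of class `mirlame_fcm`: `centroids`, `memberships`,
#'   `c`, `m`, `objective`, `objective_trace`, `iterations`, `converged`.
#' @export
fcm_cluster <- function(x, c, m = 2, tol = 1e-6, max_iter = 1000, seed = 1,
                        init_memberships = NULL) {
  X <- if (is.matrix(x)) x else as_expr_matrix(x, what = "profiles")
  n <- nrow(X)
  if (c < 2) abort("need at least 2 clusters")
  if (n <= c) abort("need more profiles than clusters")
  if (m <= 1) abort("fuzzifier m must exceed 1")

  if (is.null(init_memberships)) {
    U <- withr::with_seed(seed, matrix(runif(n * c), nrow = n))
    U <- U / rowSums(U)
  } else {
    U <- init_memberships
    stopifnot(nrow(U) == n, ncol(U) == c)
  }

  obj_trace <- numeric(0)
  V_old <- NULL
  iterations <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    Um <- U^m
    V <- (t(Um) %*% X) / colSums(Um)
    d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(V) +
      outer(rep(1, n), rowSums(V^2))
    d2 <- pmax(d2, 0)
    zero <- d2 < .Machine$double.eps
    U <- (1 / pmax(d2, .Machine$double.xmin))^(1 / (m - 1))
    U <- U / rowSums(U)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    obj_trace <- c(obj_trace, sum(U^m * d2))
    if (!is.null(V_old) && max(abs(V - V_old)) < tol) {
      converged <- TRUE
      break
    }
    V_old <- V
  }
  rownames(V) <- paste0("cluster_", seq_len(c))
  dimnames(U) <- list(rownames(X), rownames(V))

  structure(
    list(
      centroids = V, memberships = U, c = c, m = m,
      objective = obj_trace[length(obj_trace)],
      objective_trace = obj_trace,
      iterations = iterations, converged = converged
    ),
    class = "mirlame_fcm"
  )
}

#' Hard cluster assignment with membership scores
#'
#' Argmax cluster per profile (ties broken toward the lowest cluster
#' index) with the corresponding membership score.
#'
#' @param model A `mirlame_fcm` object.
#' @return Tibble `mirna_id, cluster, membership`.
#' @export
fcm_assignments <- function(model) {
  U <- model$memberships
  idx <- apply(U, 1, which.max) # which.max already prefers the lowest index
  tibble(
    mirna_id = rownames(U),
    cluster = idx,
    membership = U[cbind(seq_len(nrow(U)), idx)]
  )
}

#' Select signature miRNAs from a fuzzy clustering
#'
#' A miRNA is a signature of its argmax cluster when that membership score
#' strictly exceeds the threshold (default 0.7); a score exactly at the
#' threshold does not qualify. The resulting per-cluster sets are disjoint
#' by construction.
#'
#' @param model A `mirlame_fcm` object.
#' @param threshold Membership threshold (strict inequality).
#' @return Tibble `mirna_id, cluster, membership` of signature miRNAs.
#' @export
select_signatures <- function(model, threshold = 0.7) {
  a <- fcm_assignments(model)
  a[a$membership > threshold, ]
}

#' Call the expression trend of a consecutive-week interval
#'
#' Applies the differential-expression rule per interval: up (`U`) when
#' `log2fc > lfc_threshold` with `fdr < fdr_threshold`, down (`D`) when
#' `log2fc < -lfc_threshold` with significant FDR, otherwise no
#' significant change (`N`). Vectorized.
#'
#' @param log2fc,fdr Interval fold change(s) and adjusted p-value(s).
#' @param lfc_threshold,fdr_threshold Call-rule thresholds.
#' @return Character vector over `{"U", "N", "D"}`.
#' @export
call_trend <- function(log2fc, fdr, lfc_threshold = 1, fdr_threshold = 0.05) {
  dplyr::case_when(
    log2fc > lfc_threshold & fdr < fdr_threshold ~ "U",
    log2fc < -lfc_threshold & fdr < fdr_threshold ~ "D",
    TRUE ~ "N"
  )
}

#' Combine two interval trend calls into a temporal pattern
#'
#' Concatenates the W0-W1 and W1-W2 calls into one of the nine pattern
#' categories (`"U-D"`, `"N-N"`, ...); the mapping is a bijection from
#' call pairs onto the category set. Vectorized.
#'
#' @param t1,t2 Trend calls for the (W0, W1) and (W1, W2) intervals.
#' @return Character vector of pattern strings.
#' @export
assign_pattern <- function(t1, t2) {
  if (!all(t1 %in% TREND_LEVELS) || !all(t2 %in% TREND_LEVELS)) {
    abort("trend calls must be U, N or D")
  }
  pattern <- paste(t1, t2, sep = "-")
  stopifnot(all(pattern %in% PATTERN_LEVELS))
  pattern
}

#' Per-stratum temporal pattern table
#'
#' Runs the two-group NB Wald test between consecutive weeks within one
#' (phenotype, recovery) stratum (animals treated as independent per
#' week), calls the U/N/D trend per interval and assigns the nine-category
#' W0-W2 pattern per miRNA.
#'
#' @inheritParams build_timecourse
#' @param counts Wide count tibble (testing runs on counts, not RPM).
#' @param lfc_threshold,fdr_threshold Trend call-rule thresholds.
#' @return Tibble `mirna_id, log2fc_W0W1, fdr_W0W1, trend_W0W1,
#'   log2fc_W1W2, fdr_W1W2, trend_W1W2, pattern`. miRNAs untestable in an
#'   interval (zero counts throughout) are dropped.
#' @export
trend_patterns <- function(counts, meta, phenotype, recovery = NULL,
                           weeks = c("W0", "W1", "W2"),
                           lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(length(weeks) == 3)
  keep <- !is.na(meta$phenotype) & meta$phenotype == phenotype
  if (!is.null(recovery)) {
    keep <- keep & !is.na(meta$recovery) & meta$recovery == recovery
  }
  sub <- meta[keep, ]
  interval <- function(w_from, w_to) {
    de <- nb_wald_test(
      counts, sub, w_from, w_to,
      group_col = "week",
      lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold
    )
    tibble(
      mirna_id = de$mirna_id, log2fc = de$log2fc, fdr = de$padj,
      trend = call_trend(de$log2fc, de$padj, lfc_threshold, fdr_threshold)
    )
  }
  t1 <- interval(weeks[1], weeks[2])
  t2 <- interval(weeks[2], weeks[3])
  dplyr::inner_join(
    t1, t2,
    by = "mirna_id", suffix = c("_W0W1", "_W1W2")
  ) |>
    dplyr::mutate(pattern = assign_pattern(.data$trend_W0W1, .data$trend_W1W2))
}

#' @export
tidy.mirlame_fcm <- function(x, ...) {
  U <- x$memberships
  tibble(
    mirna_id = rep(rownames(U), ncol(U)),
    cluster = rep(seq_len(ncol(U)), each = nrow(U)),
    membership = as.vector(U)
  )
}

#' @export
glance.mirlame_fcm <- function(x, ...) {
  tibble(
    c = x$c, m = x$m, objective = x$objective,
    iterations = x$iterations, converged = x$converged,
    n_profiles = nrow(x$memberships)
  )
}

#' @export
print.mirlame_fcm <- function(x, ...) {
  cat(sprintf(
    "Fuzzy C-means fit: %d profiles, c = %d, m = %.2f\nobjective %.6g after %d iterations (%s)\n",
    nrow(x$memberships), x$c, x$m, x$objective, x$iterations,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}
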