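# Independent oracles used to cross-check the package's implementations.
# Deliberately written as plain loops so they share no code path with the
# implementations they verify.

# Brute-force AUC: concordant-pair counting over all (class0, class1)
# pairs, ties counted one half.
auc_pair_oracle <- function(values, labels) {
  x1 <- values[labels]
  x0 <- values[!labels]
  s <- 0
  for (a in x0) {
    for (b in x1) {
      s <- s + (b > a) + 0.5 * (b == a)
    }
  }
  s / (length(x0) * length(x1))
}

# Naive median-of-ratios size factors (reference = miRNAs positive in all
# samples), rescaled to geometric mean 1.
size_factor_oracle <- function(m) {
  ref <- which(apply(m, 1, function(r) all(r > 0)))
  geo <- rep(NA_real_, nrow(m))
  for (i in ref) geo[i] <- exp(mean(log(m[i, ])))
  s <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- m[ref, j] / geo[ref]
    s[j] <- median(ratios)
  }
  s / exp(mean(log(s)))
}

# Plain-loop fuzzy C-means with the standard alternating updates; started
# from the same initial membership matrix as the implementation under
# test so converged objectives are comparable.
fcm_oracle <- function(X, c, m = 2, tol = 1e-6, max_iter = 1000, init_U) {
  n <- nrow(X)
  tt <- ncol(X)
  U <- init_U
  V_old <- NULL
  obj <- NA_real_
  for (it in seq_len(max_iter)) {
    V <- matrix(0, c, tt)
    for (k in seq_len(c)) {
      num <- rep(0, tt)
      den <- 0
      for (i in seq_len(n)) {
        w <- U[i, k]^m
        num <- num + w * X[i, ]
        den <- den + w
      }
      V[k, ] <- num / den
    }
    D2 <- matrix(0, n, c)
    for (i in seq_len(n)) {
      for (k in seq_len(c)) D2[i, k] <- sum((X[i, ] - V[k, ])^2)
    }
    for (i in seq_len(n)) {
      zero <- D2[i, ] < .Machine$double.eps
      if (any(zero)) {
        U[i, ] <- zero / sum(zero)
      } else {
        for (k in seq_len(c)) {
          U[i, k] <- 1 / sum((D2[i, k] / D2[i, ])^(1 / (m - 1)))
        }
      }
    }
    obj <- 0
    for (i in seq_len(n)) {
      for (k in seq_len(c)) obj <- obj + U[i, k]^m * D2[i, k]
    }
    if (!is.null(V_old) && max(abs(V - V_old)) < tol) break
    V_old <- V
  }
  list(objective = obj, memberships = U, centroids = V)
}

# Wide expression tibble from a matrix with dimnames.
wide_tbl <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(mirna_id = rownames(m)), out)
}

# Minimal metadata for a vector of sample ids and matching group labels.
meta_for <- function(sample_ids, phenotype, week = "W0",
                     recovery = NA_character_, animal_id = NULL) {
  tibble::tibble(
    sample_id = sample_ids,
    animal_id = animal_id %||% paste0("A", seq_along(sample_ids)),
    phenotype = phenotype,
    week = week,
    gait_score = NA_integer_,
    recovery = recovery
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
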