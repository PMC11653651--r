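test_that("time courses are arithmetic means of the stratum's RPM", {
  m <- matrix(c(2, 2, 4, 4, 6, 6, 1, 3, 1, 3, 1, 3), 2, 6, byrow = TRUE,
    dimnames = list(c("a", "b"), paste0("s", 1:6))
  )
  rpm <- wide_tbl(m)
  meta <- meta_for(
    paste0("s", 1:6), "DD",
    week = rep(c("W0", "W1", "W2"), each = 2),
    recovery = "RE", animal_id = rep(c("x", "y"), 3)
  )
  tc <- build_timecourse(rpm, meta, "DD", "RE")
  expect_equal(unlist(tc[tc$mirna_id == "a", -1]), c(W0 = 2, W1 = 4, W2 = 6))
  expect_equal(unlist(tc[tc$mirna_id == "b", -1]), c(W0 = 2, W1 = 2, W2 = 2))

  expect_error(build_timecourse(rpm, meta, "DD", "UNR"), "no samples")
})

test_that("profile standardization is an exact z-score and drops constants", {
  m <- matrix(c(2, 4, 6, 5, 5, 5), 2, 3, byrow = TRUE,
    dimnames = list(c("rising", "flat"), c("W0", "W1", "W2"))
  )
  z <- standardize_profiles(wide_tbl(m))
  expect_equal(
    unlist(z[z$mirna_id == "rising", -1]),
    c(W0 = -1.2247, W1 = 0, W2 = 1.2247),
    tolerance = 1e-4
  )
  expect_equal(attr(z, "excluded"), "flat")
  zm <- as.matrix(z[-1])
  expect_true(all(abs(rowMeans(zm)) < 1e-9))
  pop_sd <- sqrt(rowMeans((zm - rowMeans(zm))^2))
  expect_true(all(abs(pop_sd - 1) < 1e-9))
})

test_that("fuzzy C-means separates well-separated profile groups", {
  withr::with_seed(2, {
    X <- rbind(
      matrix(rep(c(-1, 0, 1), each = 10), 10) + rnorm(30, sd = 0.05),
      matrix(rep(c(1, 0, -1), each = 10), 10) + rnorm(30, sd = 0.05)
    )
    rownames(X) <- sprintf("m%02d", 1:20)
  })
  fit <- fcm_cluster(X, c = 2, seed = 4)
  own <- apply(fit$memberships, 1, max)
  expect_true(all(own > 0.95))
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(diff(fit$objective_trace) < 1e-8))
})

test_that("a point equidistant from both centroids gets half memberships", {
  X <- rbind(c(-1, -1), c(-1, -1), c(1, 1), c(1, 1), c(0, 0))
  rownames(X) <- paste0("p", 1:5)
  fit <- fcm_cluster(X, c = 2, seed = 1, tol = 1e-12)
  expect_equal(unname(fit$memberships["p5", ]), c(0.5, 0.5), tolerance = 1e-5)
})

test_that("converged objective matches the plain-loop oracle on tiny instances", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      X <- matrix(rnorm(18), 6, 3)
      rownames(X) <- paste0("m", 1:6)
      U0 <- matrix(runif(12), 6, 2)
      U0 <- U0 / rowSums(U0)
      fit <- fcm_cluster(X, c = 2, init_memberships = U0)
      oracle <- fcm_oracle(X, c = 2, init_U = U0)
      expect_equal(fit$objective, oracle$objective, tolerance = 1e-6)
    }
  })
})

test_that("well-separated fits agree with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(66, {
    X <- rbind(
      matrix(rnorm(30, -3, 0.2), 10, 3), matrix(rnorm(30, 3, 0.2), 10, 3)
    )
    rownames(X) <- paste0("m", 1:20)
  })
  ours <- fcm_cluster(X, c = 2, seed = 2, tol = 1e-10)
  ref <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 500)
  # compare centroid sets up to label permutation
  ord_a <- order(ours$centroids[, 1])
  ord_b <- order(ref$centers[, 1])
  expect_equal(
    unname(ours$centroids[ord_a, ]), unname(ref$centers[ord_b, ]),
    tolerance = 1e-3
  )
})

test_that("signature selection applies the strict membership rule", {
  model <- structure(
    list(
      memberships = matrix(
        c(0.70, 0.30, 0.71, 0.29, 0.69, 0.31), 3, 2, byrow = TRUE,
        dimnames = list(c("at", "above", "below"), NULL)
      ),
      c = 2, m = 2
    ),
    class = "mirlame_fcm"
  )
  sig <- select_signatures(model, threshold = 0.7)
  expect_equal(sig$mirna_id, "above")
  expect_equal(nrow(select_signatures(model, threshold = 1)), 0)
})

test_that("signature sets are invariant to cluster relabeling", {
  withr::with_seed(5, {
    X <- rbind(
      matrix(rnorm(15, -2), 5, 3), matrix(rnorm(15, 2), 5, 3)
    )
    rownames(X) <- paste0("m", 1:10)
  })
  f1 <- fcm_cluster(X, c = 2, seed = 1)
  f2 <- f1
  f2$memberships <- f2$memberships[, 2:1]
  s1 <- select_signatures(f1)
  s2 <- select_signatures(f2)
  expect_setequal(s1$mirna_id, s2$mirna_id)
  expect_equal(
    s1$membership[order(s1$mirna_id)], s2$membership[order(s2$mirna_id)]
  )
})

test_that("trend calls follow the interval DE rule", {
  expect_equal(call_trend(1.5, 0.01), "U")
  expect_equal(call_trend(-1.2, 0.20), "N")
  expect_equal(call_trend(-1.2, 0.01), "D")
  expect_equal(call_trend(1.0, 0.001), "N") # strict > 1
})

test_that("pattern assignment is a bijection onto the nine categories", {
  grid <- expand.grid(t1 = c("U", "N", "D"), t2 = c("U", "N", "D"),
    stringsAsFactors = FALSE
  )
  patterns <- assign_pattern(grid$t1, grid$t2)
  expect_equal(length(unique(patterns)), 9)
  expect_setequal(patterns, c(
    "D-D", "D-N", "D-U", "N-D", "N-U", "N-N", "U-D", "U-N", "U-U"
  ))
  expect_equal(assign_pattern("U", "D"), "U-D")
  expect_equal(assign_pattern("N", "N"), "N-N")
  expect_error(assign_pattern("U", "X"), "U, N or D")
})

test_that("planted patterns are recovered from a synthetic cohort", {
  planted <- tibble::tibble(
    mirna_id = sprintf("sim-miR-%03d", c(15, 25, 35, 45)),
    phenotype = "DD", recovery = "UNR",
    pattern = c("U-D", "D-N", "N-U", "U-U")
  )
  hits <- unlist(lapply(1:3, function(s) {
    cfg <- simulation_config(
      n_mirnas = 100, group_sizes = c(DD = 24),
      weeks = c("W0", "W1", "W2"), recovery_fraction = 0.5,
      library_size_mean = 5e5, dispersion = 0.2, seed = 700 + s,
      planted_patterns = planted
    )
    sim <- simulate_recovery_cohort(cfg)
    pat <- trend_patterns(sim$counts, sim$metadata, "DD", "UNR")
    found <- pat$pattern[match(planted$mirna_id, pat$mirna_id)]
    found == planted$pattern
  }))
  expect_gte(mean(hits), 0.8)
})
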