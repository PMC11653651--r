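test_that("size factors match the brute-force median-of-ratios oracle", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      m <- matrix(rpois(50 * 8, 60), 50, 8,
        dimnames = list(sprintf("m%02d", 1:50), sprintf("s%d", 1:8))
      )
      expect_equal(
        unname(estimate_size_factors(wide_tbl(m), method = "ratio")),
        size_factor_oracle(m),
        tolerance = 1e-12
      )
    }
  })
})

test_that("size factors are scale-equivariant and neutral on equal samples", {
  m <- matrix(rep(c(10L, 20L, 5L), 4), 3, 4,
    dimnames = list(c("a", "b", "c"), paste0("s", 1:4))
  )
  expect_equal(unname(estimate_size_factors(wide_tbl(m))), rep(1, 4))

  m2 <- m
  m2[, 1] <- m2[, 1] * 2L
  s <- estimate_size_factors(wide_tbl(m2))
  expect_equal(unname(s[1] / s[2]), 2)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-9)
})

test_that("poscounts fallback handles matrices with no all-positive miRNA", {
  m <- matrix(c(
    0L, 10L, 10L, 10L,
    10L, 0L, 10L, 10L,
    10L, 10L, 0L, 10L
  ), 3, 4, byrow = TRUE, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_error(estimate_size_factors(wide_tbl(m), method = "ratio"), "poscounts")
  s <- estimate_size_factors(wide_tbl(m))
  expect_true(all(s > 0))
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-9)
})

test_that("dispersion estimates track the simulated truth", {
  sim_alpha <- function(alpha, seed) {
    cfg <- simulation_config(
      n_mirnas = 300, group_sizes = c(DD = 50, HC = 50),
      baseline_profile = setNames(
        rep(1 / 300, 300), sprintf("sim-miR-%03d", 1:300)
      ),
      library_size_mean = 1e5, library_size_cv = 0.1,
      dispersion = alpha, seed = seed
    )
    sim <- simulate_counts(cfg)
    sf <- estimate_size_factors(sim$counts)
    median(estimate_dispersion(sim$counts, sf, sim$metadata$phenotype))
  }
  expect_lte(sim_alpha(0, 31), 0.05)
  a04 <- sim_alpha(0.4, 32)
  expect_gte(a04, 0.2)
  expect_lte(a04, 0.6)

  const <- matrix(7L, 5, 8, dimnames = list(paste0("m", 1:5), paste0("s", 1:8)))
  sf <- setNames(rep(1, 8), paste0("s", 1:8))
  expect_equal(
    unname(estimate_dispersion(
      wide_tbl(const), sf, rep(c("A", "B"), each = 4)
    )),
    rep(0, 5)
  )
})

test_that("Wald log2fc equals the normalized group-mean ratio and flips with the contrast", {
  sim <- simulate_counts(simulation_config(
    n_mirnas = 80, group_sizes = c(DD = 8, HC = 8),
    library_size_mean = 1e5, seed = 12
  ))
  de <- nb_wald_test(sim$counts, sim$metadata, "HC", "DD")

  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$mirna_id
  m <- m[rowSums(m) > 0, ]
  sf <- estimate_size_factors(wide_tbl(m))
  k <- sweep(m, 2, sf[colnames(m)], "/")
  hc <- sim$metadata$sample_id[sim$metadata$phenotype == "HC"]
  dd <- sim$metadata$sample_id[sim$metadata$phenotype == "DD"]
  qa <- rowMeans(k[, hc])
  qb <- rowMeans(k[, dd])
  both_pos <- qa > 0 & qb > 0
  expect_equal(
    de$log2fc[match(names(qa)[both_pos], de$mirna_id)],
    unname(log2(qb / qa)[both_pos]),
    tolerance = 1e-6
  )

  rev <- nb_wald_test(sim$counts, sim$metadata, "DD", "HC")
  expect_equal(rev$log2fc, -de$log2fc)
  expect_equal(rev$pvalue, de$pvalue)

  expect_error(
    nb_wald_test(sim$counts, sim$metadata[-(1:11), ], "HC", "DD"),
    ">= 2 samples"
  )
})

test_that("the DE call rule requires both fold change and FDR", {
  de <- tibble::tibble(
    mirna_id = c("a", "b", "c"),
    log2fc = c(0.5, 1.5, -1.5),
    padj = c(1e-6, 1e-6, 0.2)
  )
  # |log2fc| <= 1 is never DE regardless of significance
  is_de <- abs(de$log2fc) > 1 & de$padj < 0.05
  expect_equal(is_de, c(FALSE, TRUE, FALSE))

  sim <- simulate_counts(simulation_config(
    n_mirnas = 100, group_sizes = c(DD = 10, HC = 10),
    library_size_mean = 2e5, seed = 40,
    planted_de = tibble::tibble(
      mirna_id = "sim-miR-050", group = "DD", log2fc = 0.5
    )
  ))
  tab <- nb_wald_test(sim$counts, sim$metadata, "HC", "DD")
  expect_false(tab$is_de[tab$mirna_id == "sim-miR-050"])
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(6, {
    p <- runif(50)
    perm <- sample(50)
    adj <- adjust_bh(p)
    expect_equal(adjust_bh(p[perm])[order(perm)], adj)
    # adjusted values never fall below the raw p and are monotone in rank
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))
  })
})

test_that("direction summaries use half-away-from-zero rounding", {
  de <- tibble::tibble(
    log2fc = c(-1.5, -1.46, -1.01, 2.67, 2.94, 4.32),
    is_de = TRUE
  )
  s <- summarize_directions(de)
  expect_equal(s$n_down, 3)
  expect_equal(s$n_up, 3)
  expect_equal(s$mean_log2fc_down, -1.32)
  expect_equal(s$mean_log2fc_up, 3.31)

  empty <- summarize_directions(tibble::tibble(log2fc = 2, is_de = FALSE))
  expect_equal(empty$n_up + empty$n_down, 0)
  expect_true(is.na(empty$mean_log2fc_up) && is.na(empty$mean_log2fc_down))

  # 0.125 rounds away from zero at 2 decimals, against banker's rounding
  s2 <- summarize_directions(
    tibble::tibble(log2fc = c(0.125, -0.125), is_de = TRUE)
  )
  expect_equal(s2$mean_log2fc_up, 0.13)
  expect_equal(s2$mean_log2fc_down, -0.13)
})

test_that("glance and tidy expose DE results in broom style", {
  sim <- simulate_counts(simulation_config(
    n_mirnas = 50, group_sizes = c(DD = 6, HC = 6),
    library_size_mean = 1e5, seed = 3
  ))
  de <- nb_wald_test(sim$counts, sim$metadata, "HC", "DD")
  g <- glance(de)
  expect_equal(g$group_b, "DD")
  expect_equal(g$n_de, g$n_up + g$n_down)
  td <- tidy(de)
  expect_false(inherits(td, "mirlame_de"))
  expect_equal(nrow(td), nrow(de))
})
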