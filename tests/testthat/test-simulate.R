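test_that("identical configurations reproduce the study byte-for-byte", {
  cfg <- simulation_config(n_mirnas = 40, seed = 9, library_size_mean = 1e5)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)

  cfg3 <- simulation_config(
    n_mirnas = 40, seed = 9, library_size_mean = 1e5,
    group_sizes = c(DD = 6, TTN = 6), weeks = c("W0", "W1", "W2")
  )
  expect_identical(
    simulate_recovery_cohort(cfg3)$counts,
    simulate_recovery_cohort(cfg3)$counts
  )
})

test_that("nothing planted means empty truth tables", {
  sim <- simulate_counts(
    simulation_config(n_mirnas = 30, seed = 1, library_size_mean = 1e5)
  )
  expect_equal(nrow(sim$truth_de), 0)
  expect_equal(nrow(sim$truth_specific), 0)
  expect_equal(nrow(sim$truth_patterns), 0)
})

test_that("planting an unknown miRNA id is a configuration error", {
  expect_error(
    simulation_config(
      n_mirnas = 30,
      planted_de = tibble::tibble(
        mirna_id = "no-such-mir", group = "DD", log2fc = 2
      )
    ),
    "absent from baseline profile"
  )
  expect_error(
    simulation_config(
      n_mirnas = 30,
      planted_patterns = tibble::tibble(
        mirna_id = "sim-miR-001", phenotype = "DD", recovery = "RE",
        pattern = "U-X"
      ),
      weeks = c("W0", "W1", "W2")
    ),
    "nine U/N/D categories"
  )
})

test_that("counts are overdispersed relative to Poisson when alpha > 0", {
  cfg <- simulation_config(
    n_mirnas = 60, group_sizes = c(DD = 60, HC = 60),
    library_size_mean = 1e5, library_size_cv = 0, dispersion = 0.4, seed = 4
  )
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  dd <- sim$metadata$sample_id[sim$metadata$phenotype == "DD"]
  sub <- m[, dd]
  mu <- rowMeans(sub)
  v <- apply(sub, 1, var)
  keep <- mu > 20
  # variance/mean ratio ~ 1 + alpha * mu >> 1 at these abundances
  expect_gt(median((v / mu)[keep]), 2)
})

test_that("configured top-10 read share is observed empirically", {
  shares <- vapply(1:5, function(s) {
    sim <- simulate_counts(simulation_config(
      n_mirnas = 150, group_sizes = c(HC = 12, DD = 12),
      library_size_mean = 2e6, seed = 100 + s
    ))
    top_expressed_share(rpm_normalize(sim$counts), k = 10)$share
  }, numeric(1))
  expect_true(all(abs(shares - 0.85) < 0.03))
})

test_that("recovery cohort follows the gait-score recovery rule", {
  cfg <- simulation_config(
    n_mirnas = 30, group_sizes = c(DD = 10, TTN = 6),
    weeks = c("W0", "W1", "W2"), recovery_fraction = 1,
    library_size_mean = 1e5, seed = 21
  )
  sim <- simulate_recovery_cohort(cfg)
  expect_true(all(sim$truth_recovery$recovery == "RE"))
  expect_true(all(sim$metadata$gait_score %in% 0:3))
  traj <- tidyr::pivot_wider(
    sim$metadata[c("animal_id", "week", "gait_score")],
    names_from = "week", values_from = "gait_score"
  )
  expect_true(all(traj$W1 <= traj$W0 & traj$W2 <= traj$W1))
  expect_true(all(traj$W2 < traj$W0))

  cfg0 <- simulation_config(
    n_mirnas = 30, group_sizes = c(DD = 10), weeks = c("W0", "W1", "W2"),
    recovery_fraction = 0, library_size_mean = 1e5, seed = 21
  )
  sim0 <- simulate_recovery_cohort(cfg0)
  traj0 <- tidyr::pivot_wider(
    sim0$metadata[c("animal_id", "week", "gait_score")],
    names_from = "week", values_from = "gait_score"
  )
  expect_true(all(sim0$truth_recovery$recovery == "UNR"))
  expect_true(all(traj0$W1 >= traj0$W0 & traj0$W2 >= traj0$W1))

  expect_error(
    simulate_recovery_cohort(
      simulation_config(n_mirnas = 30, group_sizes = c(DD = 4), weeks = "W0")
    ),
    "three weeks"
  )
})

test_that("planted temporal patterns shift the stratum group means", {
  target <- "sim-miR-020"
  hits <- vapply(1:5, function(s) {
    cfg <- simulation_config(
      n_mirnas = 60, group_sizes = c(DD = 16),
      weeks = c("W0", "W1", "W2"), recovery_fraction = 0.5,
      library_size_mean = 5e5, dispersion = 0.2, seed = 300 + s,
      planted_patterns = tibble::tibble(
        mirna_id = target, phenotype = "DD", recovery = "UNR",
        pattern = "U-D"
      )
    )
    sim <- simulate_recovery_cohort(cfg)
    tc <- build_timecourse(
      rpm_normalize(sim$counts), sim$metadata, "DD", "UNR"
    )
    prof <- unlist(tc[tc$mirna_id == target, -1])
    prof["W1"] > prof["W0"] && prof["W2"] < prof["W1"]
  }, logical(1))
  expect_true(all(hits))
})

test_that("zero-noise Ct tables recover planted fold changes exactly", {
  cfg <- simulation_config(
    n_mirnas = 20, group_sizes = c(HC = 6, DD = 6), seed = 5
  )
  fc <- tibble::tibble(target = "t1", group = "DD", fold_change = 4)
  sim <- simulate_ct_table(cfg, fc, refs = c("r1", "r2"), noise_sd = 0)
  rel <- delta_delta_ct(sim$ct, sim$metadata, "t1", c("r1", "r2"), "HC")
  expect_equal(rel$fold_change[rel$group == "DD"], rep(4, 6))
  expect_equal(rel$fold_change[rel$group == "HC"], rep(1, 6))

  expect_error(
    simulate_ct_table(cfg, fc, refs = c("r1", "r1")),
    "two distinct reference"
  )
})

test_that("noisy Ct fold-change recovery stays within a factor of sqrt(2)", {
  # 10 replicates per group, planted fold 8, Ct noise sd 0.2 cycles
  ok <- vapply(1:100, function(s) {
    cfg <- simulation_config(
      n_mirnas = 20, group_sizes = c(HC = 10, DD = 10), seed = 1000 + s
    )
    sim <- simulate_ct_table(
      cfg, tibble::tibble(target = "t1", group = "DD", fold_change = 8),
      refs = c("r1", "r2"), noise_sd = 0.2
    )
    rel <- delta_delta_ct(sim$ct, sim$metadata, "t1", c("r1", "r2"), "HC")
    est <- exp(mean(log(rel$fold_change[rel$group == "DD"])))
    est >= 5.7 && est <= 11.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
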