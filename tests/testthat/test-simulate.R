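test_that("Balding-Nichols draws have the model's mean and variance", {
  expect_equal(balding_nichols_freqs(0.3, 0), c(0.3, 0.3))
  set.seed(14)
  d <- replicate(5000, balding_nichols_freqs(0.3, 0.15)[1])
  se_mean <- sqrt(0.15 * 0.3 * 0.7 / 5000)
  expect_lt(abs(mean(d) - 0.3), 3 * se_mean)
  expect_lt(abs(var(d) - 0.15 * 0.3 * 0.7) / (0.15 * 0.3 * 0.7), 0.12)
  expect_error(balding_nichols_freqs(0, 0.1), "ancestral")
  expect_error(balding_nichols_freqs(0.3, 1), "fst")
})

test_that("LD blocks decay with distance and keep Hardy-Weinberg proportions", {
  set.seed(25)
  G0 <- simulate_ld_genotypes(4000, rep(0.3, 10), ld_rho = 0)
  r2_adj <- sapply(1:9, function(j) cor(G0[, j], G0[, j + 1])^2)
  expect_lt(mean(r2_adj), 0.01)
  G9 <- simulate_ld_genotypes(4000, rep(0.3, 10), ld_rho = 0.9)
  r2a <- mean(sapply(1:9, function(j) cor(G9[, j], G9[, j + 1])^2))
  r2c <- mean(sapply(1:7, function(j) cor(G9[, j], G9[, j + 3])^2))
  expect_gt(r2a, r2c)
  # HWE chi-square rejects at about the nominal 1% rate
  set.seed(26)
  Gh <- simulate_ld_genotypes(800, runif(400, 0.1, 0.5), ld_rho = 0.5)
  pv <- apply(Gh, 2, function(col) hwe_chisq(.count3(col))$p_value)
  rate <- mean(pv < 0.01)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 400) + 0.005)
  expect_error(simulate_ld_genotypes(10, 0.3, ld_rho = 1), "ld_rho")
})

test_that("simulated cohorts honour counts, matching and reproducibility", {
  ann <- pathway_annotation()
  small <- ann[ann$gene %in% c("IL10", "COX2") | ann$is_aim, ]
  cfg <- sim_config(n_cases = 80, n_controls = 90, pool_mult = 10,
                    annotation = small, seed = 33)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$samples$status == 1), 80)
  expect_equal(sum(sim$samples$status == 0), 90)
  # byte-identical rerun under the same seed
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$genotypes$calls, sim2$genotypes$calls)
  expect_identical(sim$samples, sim2$samples)
  # matched controls mirror the cases' ethnicity x age-bin distribution
  bins <- function(s) table(paste(s$ethnicity,
                                  floor((s$age - 40) / 5)))
  cb <- bins(sim$samples[sim$samples$status == 1, ])
  kb <- bins(sim$samples[sim$samples$status == 0, ])
  shared <- intersect(names(cb), names(kb))
  expect_gte(length(shared), 1)
  expect_lt(max(abs(kb[shared] / 90 - cb[shared] / 80)), 0.05)
})

test_that("AIM frequency differentials are realized as configured", {
  ann <- pathway_annotation()
  cfg <- sim_config(n_cases = 150, n_controls = 150, pool_mult = 6,
                    aim_delta = 0.3,
                    annotation = ann[ann$gene %in% "IL10" | ann$is_aim, ],
                    seed = 44)
  sim <- simulate_cohort(cfg)
  aims <- sim$annotation$snp_id[sim$annotation$is_aim]
  g1 <- sim$samples$ethnicity == "group1"
  f1 <- colMeans(sim$genotypes$calls[g1, aims]) / 2
  f2 <- colMeans(sim$genotypes$calls[!g1, aims]) / 2
  # mean absolute differential near 0.3 (clipping shrinks extremes slightly)
  expect_gt(mean(abs(f2 - f1)), 0.2)
  expect_lt(mean(abs(f2 - f1)), 0.4)
})

test_that("a null cohort yields calibrated kernel-test p-values downstream", {
  ann <- pathway_annotation()
  sub <- ann[ann$gene %in% c("IL10", "TLR6") | ann$is_aim, ]
  pv <- numeric(40)
  for (i in seq_len(40)) {
    cfg <- sim_config(n_cases = 60, n_controls = 60, pool_mult = 20,
                      annotation = sub, seed = 500 + i)
    sim <- simulate_cohort(cfg)
    h <- build_hierarchy(sim$annotation)
    res <- run_set_tests(sim$genotypes, sim$samples, h,
                         covariates = c("age", "ethnicity"))
    pv[i] <- res$p_value[res$level == "pathway"]
  }
  # no gross inflation at the pathway level under the null
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
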