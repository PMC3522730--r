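test_that("genotype codings produce the documented design columns", {
  expect_equal(code_genotypes(c(0, 1, 2), "codominant"),
               cbind(het = c(0, 1, 0), hom = c(0, 0, 1)))
  expect_equal(code_genotypes(c(0, 1, 2), "log-additive"),
               cbind(trend = c(0, 1, 2)))
  expect_error(code_genotypes(c(0, 3), "codominant"), "0, 1, 2")
})

test_that("no-covariate codominant ORs equal contingency cross-products", {
  cc <- cohort_from_counts(cases = c(100, 80, 20), controls = c(100, 100, 10))
  res <- assoc_single_snp(cc$gm, cc$samples, "snpX", "codominant",
                          covariates = character(0))
  het <- res[res$contrast == "het", ]
  hom <- res[res$contrast == "hom", ]
  expect_equal(het$or, (80 * 100) / (100 * 100), tolerance = 1e-6)
  expect_equal(hom$or, (20 * 100) / (10 * 100), tolerance = 1e-6)
  # closed-form Wald interval for the heterozygote contrast
  se <- sqrt(1 / 100 + 1 / 80 + 1 / 100 + 1 / 100)
  expect_equal(het$ci_low, 0.8 * exp(-1.959964 * se), tolerance = 1e-6)
  expect_equal(het$ci_high, 0.8 * exp(1.959964 * se), tolerance = 1e-6)
})

test_that("adjusted fits agree with the direct-likelihood oracle", {
  tc <- make_test_cohort(n = 150, p = 1, seed = 61, maf = 0.35)
  res <- assoc_single_snp(tc$gm, tc$samples, "snp01", "log-additive",
                          covariates = c("age"))
  calls <- tc$gm$calls[, 1]
  X <- cbind(1, calls, tc$samples$age)
  b <- oracle_logistic_mle(tc$samples$status, X)
  expect_equal(log(res$or[res$contrast == "trend"]), b[2],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("empty status-by-genotype cells render contrasts undefined", {
  cc <- cohort_from_counts(cases = c(100, 30, 0), controls = c(100, 25, 5))
  res <- assoc_single_snp(cc$gm, cc$samples, "snpX", "codominant",
                          covariates = character(0))
  expect_false(res$defined[res$contrast == "hom"])
  expect_true(is.na(res$or[res$contrast == "hom"]))
  expect_true(res$defined[res$contrast == "het"])
  # rare homozygotes absent from the whole stratum: trend drops the level
  cc2 <- cohort_from_counts(cases = c(100, 30, 0), controls = c(100, 25, 0))
  res2 <- assoc_single_snp(cc2$gm, cc2$samples, "snpX", "log-additive",
                           covariates = character(0))
  expect_true(res2$defined[res2$contrast == "trend"])
  # monomorphic stratum: nothing testable
  cc3 <- cohort_from_counts(cases = c(100, 0, 0), controls = c(100, 0, 0))
  res3 <- assoc_single_snp(cc3$gm, cc3$samples, "snpX", "log-additive",
                           covariates = character(0))
  expect_false(res3$defined)
})

test_that("trend OR inverts under flipping the reference homozygote", {
  tc <- make_test_cohort(n = 200, p = 1, seed = 71, maf = 0.4)
  r1 <- assoc_single_snp(tc$gm, tc$samples, "snp01", "log-additive",
                         covariates = character(0))
  gm2 <- tc$gm
  gm2$calls[, 1] <- 2 - gm2$calls[, 1]
  r2 <- assoc_single_snp(gm2, tc$samples, "snp01", "log-additive",
                         covariates = character(0))
  expect_equal(r1$or, 1 / r2$or, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("stratified runs handle per-stratum undefined contrasts", {
  set.seed(5)
  n <- 160
  eth <- rep(c("group1", "group2"), c(120, 40))
  calls <- ifelse(eth == "group1", rbinom(n, 2, 0.3), 0)  # monomorphic in group2
  gm <- genotype_matrix(matrix(calls, ncol = 1), sprintf("s%03d", 1:n), "rsZ")
  sam <- data.frame(sample_id = sprintf("s%03d", 1:n),
                    status = rbinom(n, 1, 0.5), age = runif(n, 50, 80),
                    institution = "a", ethnicity = eth,
                    stringsAsFactors = FALSE)
  res <- assoc_single_snp(gm, sam, "rsZ", "log-additive",
                          covariates = "age", strata = "ethnicity")
  expect_true(res$defined[res$stratum == "overall"])
  expect_false(res$defined[res$stratum == "group2"])
})

test_that("planted per-allele effects are recovered without bias", {
  # protective trend OR of 0.75 at MAF 0.3, moderately sized cohorts
  set.seed(55)
  or_true <- 0.75
  reps <- 60
  est <- cover <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- rbinom(700, 2, 0.3)
    y <- rbinom(700, 1, plogis(0.4 + log(or_true) * g))
    sam <- data.frame(sample_id = sprintf("s%03d", 1:700), status = y,
                      age = 60, institution = "a", ethnicity = "e",
                      stringsAsFactors = FALSE)
    gm <- genotype_matrix(matrix(g, ncol = 1), sam$sample_id, "rs1")
    r <- assoc_single_snp(gm, sam, "rs1", "log-additive",
                          covariates = character(0))
    est[i] <- r$or
    cover[i] <- r$ci_low <= or_true && or_true <= r$ci_high
  }
  expect_lt(abs(mean(est) - or_true) / or_true, 0.05)
  expect_gte(mean(cover), 0.85)
})
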