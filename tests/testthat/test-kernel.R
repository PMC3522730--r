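test_that("intercept-only null model recovers the case fraction in closed form", {
  n1 <- 494; n0 <- 536
  sam <- data.frame(sample_id = sprintf("s%04d", 1:(n1 + n0)),
                    status = rep(c(1, 0), c(n1, n0)), age = 60,
                    institution = "a", ethnicity = "e1",
                    stringsAsFactors = FALSE)
  null <- fit_null_logistic(sam, covariates = character(0))
  expect_equal(unique(round(null$fitted, 10)), round(n1 / (n1 + n0), 10))
  expect_equal(unname(null$coefficients[1]), log(n1 / n0), tolerance = 1e-8)
})

test_that("null model coefficients match a direct likelihood-maximization oracle", {
  tc <- make_test_cohort(n = 90, p = 2, seed = 31)
  null <- fit_null_logistic(tc$samples, c("age", "institution"))
  b <- oracle_logistic_mle(null$y, null$design)
  expect_equal(unname(null$coefficients), b, tolerance = 1e-6)
})

test_that("separation and constant covariates raise explicit errors", {
  tc <- make_test_cohort(n = 40, p = 2, seed = 8)
  sam <- tc$samples
  sam$sep <- sam$status  # perfect separation
  expect_error(suppressWarnings(fit_null_logistic(sam, "sep")),
               "separation|converge")
  sam$const <- 1
  expect_error(fit_null_logistic(sam, "const"), "constant")
})

test_that("linear kernel is G G' with the documented edge cases", {
  expect_equal(linear_kernel(diag(2)), diag(2))
  set.seed(44)
  G <- matrix(rbinom(60, 2, 0.3), 10, 6)
  K <- linear_kernel(G)
  expect_equal(K, t(K))
  expect_true(all(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-10))
  G2 <- rbind(G, G[1, ])                     # duplicated sample row
  K2 <- linear_kernel(G2)
  expect_equal(K2[1, ], K2[11, ])
  expect_error(linear_kernel(matrix(0, 3, 0)), "empty")
})

test_that("Q matches its brute-force definition and rank-1 algebra", {
  tc <- make_test_cohort(n = 20, p = 5, seed = 13)
  null <- fit_null_logistic(tc$samples, "age")
  G <- mean_impute(tc$gm)
  r <- null$y - null$fitted
  expect_equal(skat_statistic(null, linear_kernel(G)),
               drop(t(r) %*% G %*% t(G) %*% r), tolerance = 1e-10)
  g <- G[, 1]
  expect_equal(skat_statistic(null, linear_kernel(cbind(g))),
               sum(g * r)^2, tolerance = 1e-10)
  # zero residuals give Q = 0
  expect_equal(drop(crossprod(rep(0, 20),
                              linear_kernel(G) %*% rep(0, 20))), 0)
})

test_that("null spectrum matches the explicit n x n projected-kernel eigenvalues", {
  tc <- make_test_cohort(n = 30, p = 4, seed = 17)
  null <- fit_null_logistic(tc$samples, c("age", "institution"))
  G <- mean_impute(tc$gm)[, 1:4]
  v <- null$weights; X <- null$design
  P0 <- diag(v) - (X * v) %*% solve(crossprod(X, X * v), t(X * v))
  K <- linear_kernel(G)
  ev_full <- eigen(P0 %*% K, only.values = TRUE)$values
  ev_full <- sort(Re(ev_full[Re(ev_full) > 1e-8]), decreasing = TRUE)
  lam <- null_spectrum(null, G)
  expect_equal(lam, ev_full, tolerance = 1e-8)
  # conservation: sum of weights equals trace(P0 K)
  expect_equal(sum(lam), sum(diag(P0 %*% K)), tolerance = 1e-8)
  # rank-1: single lambda = g' P0 g
  g <- G[, 2, drop = FALSE]
  expect_equal(null_spectrum(null, g), drop(t(g) %*% P0 %*% g),
               tolerance = 1e-8)
})

test_that("quadratic-form p-values equal chi-square closed forms and the oracle", {
  expect_equal(quadform_pvalue(3.841459, 1)$p_value, 0.05, tolerance = 1e-6)
  expect_equal(quadform_pvalue(5.991465, c(1, 1))$p_value, 0.05,
               tolerance = 1e-6)
  r <- quadform_pvalue(8, c(2, 1, 0.5))
  expect_lt(abs(r$p_value - oracle_quadform_p(8, c(2, 1, 0.5))), 1e-6)
  expect_identical(r$method, "davies")
  expect_equal(quadform_pvalue(5, c(0, 0))$p_value, 1)
  expect_error(quadform_pvalue(-1, 1), "non-negative")
})

test_that("Davies and Liu engines agree in the central range", {
  set.seed(3)
  for (i in 1:30) {
    lam <- runif(sample(5:12, 1), 0.3, 2)
    q <- sum(lam) * runif(1, 0.5, 2)
    d <- quadform_pvalue(q, lam)$p_value
    l <- quadform_pvalue(q, lam, method = "liu")$p_value
    if (d > 0.01 && d < 0.99) expect_lt(abs(d - l), 0.05)
  }
})

test_that("single-SNP set p equals the 1-df score test p to 1e-8", {
  tc <- make_test_cohort(n = 150, p = 3, seed = 23)
  sam <- tc$samples
  null <- fit_null_logistic(sam, c("age", "institution"))
  G <- mean_impute(tc$gm)
  for (j in 1:3) {
    res <- kernel_set_test(null, G[, j, drop = FALSE])
    sc <- single_snp_score_tests(null, G[, j, drop = FALSE])
    expect_equal(res$p_value, sc$p_value, tolerance = 1e-8)
  }
})

test_that("set results are invariant under SNP order permutation within a set", {
  tc <- make_test_cohort(n = 100, p = 8, seed = 29)
  null <- fit_null_logistic(tc$samples, "age")
  G <- mean_impute(tc$gm)
  set.seed(1)
  perm <- sample(8)
  a <- kernel_set_test(null, G)
  b <- kernel_set_test(null, G[, perm])
  expect_equal(a$Q, b$Q, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
})

test_that("Davies p agrees with an empirical permutation p", {
  set.seed(42)
  n <- 200; p <- 5
  G <- simulate_ld_genotypes(n, runif(p, 0.2, 0.45), ld_rho = 0.4)
  colnames(G) <- sprintf("s%d", 1:p)
  y <- rbinom(n, 1, 0.45)
  sam <- data.frame(sample_id = sprintf("x%03d", 1:n), status = y,
                    age = 60, institution = "a", ethnicity = "e",
                    stringsAsFactors = FALSE)
  null <- fit_null_logistic(sam, character(0))
  res <- kernel_set_test(null, G)
  B <- 10000
  K <- linear_kernel(G)
  # label permutation keeps the intercept-only fitted mean fixed
  R <- replicate(B, sample(y) - mean(y))
  Qb <- colSums((K %*% R) * R)
  p_perm <- (1 + sum(Qb >= res$Q)) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(res$p_value - p_perm), 3 * se + 1 / B)
})

test_that("hierarchy-driven set tests report every level and flag 1-SNP genes", {
  tc <- make_test_cohort(n = 120, p = 7, seed = 37)
  ann <- data.frame(
    snp_id = tc$gm$snp_ids, chrom = 1, pos = 1:7,
    gene = c("G1", "G1", "G1", "G2", "G2", "G2", "G3"),
    subpathway = rep(c("cytokine signaling", "selenoproteins"), c(3, 4)),
    is_aim = FALSE, stringsAsFactors = FALSE)
  h <- build_hierarchy(ann)
  res <- run_set_tests(tc$gm, tc$samples, h,
                       covariates = c("age", "institution"),
                       strata = "ethnicity")
  overall <- res[res$stratum == "overall", ]
  expect_equal(sum(overall$level == "pathway"), 1)
  expect_equal(sum(overall$level == "subpathway"), 2)
  expect_equal(sum(overall$level == "gene"), 3)
  g3 <- overall[overall$set == "G3", ]
  expect_identical(g3$method, "not_tested")
  expect_true(is.na(g3$p_value))
  expect_setequal(unique(res$stratum), c("overall", "group1", "group2"))
  # missing SNP ids in the hierarchy are reported
  h2 <- build_test_hierarchy(c(tc$gm$snp_ids, "ghost"))
  expect_error(run_set_tests(tc$gm, tc$samples, h2, covariates = "age"),
               "ghost")
})
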