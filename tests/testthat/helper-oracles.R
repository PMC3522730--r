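# Independent oracles used to cross-check the package's own routes.

# Tail probability of sum(lambda_j chi^2_1) > q by characteristic-function
# inversion on a fixed Simpson grid with an analytic tail bound -- coded
# independently of the package's adaptive-quadrature engine.
oracle_quadform_p <- function(q, lambda, tol = 1e-8) {
  k <- length(lambda)
  c_half <- prod(sqrt(lambda))
  U <- max((2 / (pi * k * c_half * tol))^(2 / k), 1)
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rh <- exp(0.25 * colSums(log1p(outer(lambda, u)^2)))
    ifelse(u == 0, 0.5 * (sum(lambda) - q), sin(th) / (u * rh))
  }
  m <- 2^as.integer(max(16, min(22, ceiling(log2(U * max(q, 1) * 8)))))
  u <- seq(0, U, length.out = m + 1)
  w <- c(1, rep(c(4, 2), length.out = m - 1), 1)
  0.5 + sum(w * f(u)) * (U / m) / 3 / pi
}

# Direct maximum-likelihood logistic fit via general-purpose optimisation
# (no IRLS), as an oracle for glm-based fits.
oracle_logistic_mle <- function(y, X) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) drop(crossprod(X, plogis(drop(X %*% b)) - y))
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  fit$par
}

# Hand-computed Hardy-Weinberg chi-square from expected counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# A small aligned genotype matrix + sample table for unit tests.
make_test_cohort <- function(n = 80, p = 6, seed = 1, maf = 0.3,
                             missing = 0) {
  set.seed(seed)
  calls <- matrix(rbinom(n * p, 2, maf), n, p)
  if (missing > 0) calls[runif(n * p) < missing] <- NA
  ids <- sprintf("T%03d", seq_len(n))
  snps <- sprintf("snp%02d", seq_len(p))
  gm <- genotype_matrix(calls, ids, snps)
  samples <- data.frame(
    sample_id = ids, status = rbinom(n, 1, 0.5),
    age = runif(n, 45, 85),
    institution = sample(c("site1", "site2"), n, replace = TRUE),
    ethnicity = sample(c("group1", "group2"), n, replace = TRUE,
                       prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  list(gm = gm, samples = samples)
}

.count3 <- function(col)
  c(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
    sum(col == 2, na.rm = TRUE))

# Minimal hierarchy over ad-hoc SNP ids: two genes in one sub-pathway.
build_test_hierarchy <- function(snp_ids) {
  half <- ceiling(length(snp_ids) / 2)
  ann <- data.frame(
    snp_id = snp_ids, chrom = 1, pos = seq_along(snp_ids),
    gene = rep(c("GENE1", "GENE2"), c(half, length(snp_ids) - half)),
    subpathway = "cytokine signaling", is_aim = FALSE,
    stringsAsFactors = FALSE)
  build_hierarchy(ann)
}

# Genotype counts laid out as calls, for contingency-table oracles:
# counts = list(cases = c(n0, n1, n2), controls = c(n0, n1, n2)).
cohort_from_counts <- function(cases, controls) {
  calls <- c(rep(0:2, cases), rep(0:2, controls))
  status <- rep(c(1, 0), c(sum(cases), sum(controls)))
  ids <- sprintf("C%04d", seq_along(calls))
  gm <- genotype_matrix(matrix(calls, ncol = 1), ids, "snpX")
  samples <- data.frame(sample_id = ids, status = status,
                        age = 60, institution = "site1",
                        ethnicity = "group1", stringsAsFactors = FALSE)
  list(gm = gm, samples = samples)
}
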