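#' Fit the covariate-only (null) logistic model
#'
#' Regresses case status on the adjustment covariates only (default: age,
#' institution as indicator contrasts, and the first ancestry principal
#' component). The fitted means, design matrix and IRLS weights
#' `v_i = mu_i (1 - mu_i)` are the building blocks of the kernel score test.
#' Fitting is iteratively reweighted least squares with a tight convergence
#' tolerance; non-convergence and (quasi-)separation raise errors rather than
#' returning unusable coefficients.
#'
#' @param samples Sample table with a `status` column and the covariates.
#' @param covariates Character vector of covariate column names; empty vector
#'   fits an intercept-only model. Factors/characters enter as indicator
#'   contrasts.
#' @return An object of class `null_model`: list with `coefficients`,
#'   `fitted` (means in (0,1)), `design` (model matrix X with intercept),
#'   `weights` (v), `y`, `sample_id`, `formula`.
#' @export
fit_null_logistic <- function(samples,
                              covariates = c("age", "institution",
                                             "ancestry_pc1")) {
  samples <- validate_samples(samples)
  missing_cov <- setdiff(covariates, names(samples))
  if (length(missing_cov))
    stop("covariate(s) not in sample table: ",
         paste(missing_cov, collapse = ", "))
  dat <- samples[, c("status", covariates), drop = FALSE]
  for (v in covariates) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    vals <- dat[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L)
      stop("covariate '", v, "' is constant")
  }
  if (anyNA(dat)) stop("missing values in status or covariates")
  form <- if (length(covariates))
    stats::as.formula(paste("status ~", paste(sprintf("`%s`", covariates),
                                              collapse = " + ")))
  else stats::as.formula("status ~ 1")
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged)
    stop("null logistic model did not converge in 100 IRLS iterations ",
         "(deviance ", signif(fit$deviance, 6), ")")
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)) > 15))
    stop("null logistic model shows (quasi-)separation: fitted ",
         "probabilities at the boundary or diverging coefficients")
  X <- stats::model.matrix(fit)
  n <- nrow(X)
  if (n <= ncol(X)) stop("more coefficients than samples")
  structure(list(coefficients = stats::coef(fit), fitted = as.numeric(mu),
                 design = X, weights = as.numeric(mu * (1 - mu)),
                 y = dat$status, sample_id = samples$sample_id,
                 formula = form),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("null_model:", length(x$y), "samples,", ncol(x$design),
      "coefficients\n")
  print(x$coefficients)
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call by its SNP's mean observed count, the standard
#' preparation before forming the linear kernel.
#'
#' @param gm A `genotype_matrix` (or plain matrix).
#' @return A numeric matrix with no missing values.
#' @export
mean_impute <- function(gm) {
  x <- if (inherits(gm, "genotype_matrix")) gm$calls else as.matrix(gm)
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) {
      m <- mean(x[!na, j])
      if (!is.finite(m)) stop("SNP column ", j, " is entirely missing")
      x[na, j] <- m
    }
  }
  x
}

#' Linear kernel K = G G'
#'
#' Genetic similarity between individuals as the inner product of their
#' minor-allele-count vectors over the SNP set (unweighted).
#'
#' @param G Numeric matrix, samples x SNPs, no missing values.
#' @return Symmetric positive semidefinite n x n matrix.
#' @export
linear_kernel <- function(G) {
  G <- as.matrix(G)
  if (ncol(G) == 0L) stop("empty SNP set: kernel undefined")
  if (anyNA(G)) stop("kernel requires complete genotypes; mean-impute first")
  tcrossprod(G)
}

#' Variance-component score statistic Q
#'
#' `Q = (y - mu)' K (y - mu)` with `mu` the null-model fitted means; under
#' the null hypothesis of no SNP-set effect Q follows a mixture of 1-df
#' chi-square distributions with weights given by [null_spectrum()].
#'
#' @param null A `null_model`.
#' @param K Kernel matrix from [linear_kernel()].
#' @return Non-negative scalar.
#' @export
skat_statistic <- function(null, K) {
  stopifnot(inherits(null, "null_model"))
  r <- null$y - null$fitted
  if (nrow(K) != length(r) || ncol(K) != length(r))
    stop("kernel dimension (", nrow(K), ") does not match sample size (",
         length(r), ")")
  drop(crossprod(r, K %*% r))
}

#' Mixture weights of the null distribution of Q
#'
#' Eigenvalues of `P0^(1/2) K P0^(1/2)` where
#' `P0 = V - V X (X' V X)^-1 X' V` is the projected IRLS weight matrix of the
#' null model. Computed on the p x p matrix `G' P0 G`, which shares the
#' non-zero spectrum; eigenvalues below `1e-10 * max` are discarded as
#' numerical zeros.
#'
#' @param null A `null_model`.
#' @param G Genotype submatrix (samples x SNPs), complete.
#' @return Non-negative eigenvalues, decreasing.
#' @export
null_spectrum <- function(null, G) {
  stopifnot(inherits(null, "null_model"))
  G <- as.matrix(G)
  v <- null$weights
  if (!all(is.finite(v))) stop("non-finite null-model weights")
  if (nrow(G) != length(v))
    stop("genotype rows (", nrow(G), ") do not match sample size (",
         length(v), ")")
  X <- null$design
  GV <- G * v                                   # V G, rows scaled
  GtVG <- crossprod(G, GV)
  GtVX <- crossprod(GV, X)                      # G' V X
  XtVX <- crossprod(X, X * v)
  A <- GtVG - GtVX %*% solve(XtVX, t(GtVX))
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (!length(ev)) return(numeric(0))
  ev[ev < 0] <- 0
  ev[ev >= 1e-10 * max(ev, 0)]
}

# Imhof integrand for P(sum lambda_j chi2_1 > q); vectorized in u
.imhof_integrand <- function(u, lambda, q) {
  lu <- outer(lambda, u)                        # p x m
  theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
  rho <- exp(0.25 * colSums(log1p(lu^2)))
  out <- sin(theta) / (u * rho)
  out[u == 0] <- 0.5 * (sum(lambda) - q)        # limit as u -> 0
  out
}

# Characteristic-function inversion (Imhof's formula, adaptive quadrature)
.davies_pvalue <- function(q, lambda, acc = 1e-6) {
  val <- tryCatch(
    stats::integrate(.imhof_integrand, 0, Inf, lambda = lambda, q = q,
                     abs.tol = acc / 2, rel.tol = acc,
                     subdivisions = 10000L),
    error = function(e) NULL)
  if (is.null(val) || val$message != "OK") return(NA_real_)
  0.5 + val$value / pi
}

# Liu et al. moment-matching approximation (modified, kurtosis-based)
.liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + d; sigma_x <- sqrt(2) * a
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = d, lower.tail = FALSE)
}

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' `P(sum_j lambda_j chi^2_1 > q)`, the p-value of the variance-component
#' score statistic. The default engine inverts the characteristic function
#' numerically (Imhof's formula, Davies-style exact inversion) to absolute
#' accuracy `acc`; if the inversion fails or falls outside `[0, 1]` the Liu
#' moment-matching chi-square approximation is used and recorded.
#'
#' @param q Observed statistic (non-negative scalar).
#' @param lambda Non-negative mixture weights.
#' @param method `"davies"` (inversion with Liu fallback) or `"liu"`.
#' @param acc Absolute accuracy of the inversion (default 1e-6).
#' @return List with `p_value` and `method` (the engine actually used).
#' @export
quadform_pvalue <- function(q, lambda, method = c("davies", "liu"),
                            acc = 1e-6) {
  method <- match.arg(method)
  if (length(q) != 1L || !is.finite(q) || q < 0)
    stop("q must be a single non-negative number")
  if (any(lambda < -1e-12)) stop("negative mixture weight")
  lambda <- lambda[lambda > 0]
  if (!length(lambda))
    return(list(p_value = 1, method = "degenerate"))
  # equal weights: exactly a scaled chi-square, no inversion needed
  if (max(lambda) - min(lambda) <= 1e-12 * max(lambda))
    return(list(p_value = stats::pchisq(q / lambda[1], df = length(lambda),
                                        lower.tail = FALSE),
                method = "davies"))
  if (method == "davies") {
    p <- .davies_pvalue(q, lambda, acc)
    if (!is.na(p) && p >= -acc && p <= 1 + acc)
      return(list(p_value = min(max(p, 0), 1), method = "davies"))
  }
  list(p_value = .liu_pvalue(q, lambda), method = "liu")
}

#' Kernel-machine score test for one SNP set
#'
#' @param null A `null_model`.
#' @param G Complete genotype submatrix for the set (samples x SNPs).
#' @param method P-value engine, see [quadform_pvalue()].
#' @return List with `Q`, `lambda`, `p_value`, `method`, `snp_count`.
#' @export
kernel_set_test <- function(null, G, method = "davies") {
  G <- as.matrix(G)
  Q <- skat_statistic(null, linear_kernel(G))
  lam <- null_spectrum(null, G)
  pv <- quadform_pvalue(Q, lam, method = method)
  list(Q = Q, lambda = lam, p_value = pv$p_value, method = pv$method,
       snp_count = ncol(G))
}

# covariates usable within a stratum: drop those constant there
.stratum_covariates <- function(samples, covariates) {
  keep <- vapply(covariates, function(v) {
    length(unique(samples[[v]])) > 1L
  }, logical(1))
  covariates[keep]
}

#' Run the kernel test over a pathway hierarchy
#'
#' One test per pathway, per sub-pathway, and per gene with at least two
#' SNPs; single-SNP genes are reported as not tested. Optionally repeated
#' within strata (e.g. per ethnicity), where covariates that are constant
#' within a stratum are dropped from the null model.
#'
#' @param gm A QC'd `genotype_matrix` (missing calls are mean-imputed here).
#' @param samples Aligned sample table containing the covariates.
#' @param hierarchy A `pathway_hierarchy`.
#' @param covariates Null-model covariates (default age, institution,
#'   ancestry_pc1).
#' @param strata Optional column name (e.g. `"ethnicity"`); adds per-stratum
#'   runs to the overall one.
#' @param method P-value engine, see [quadform_pvalue()].
#' @return Data frame with columns `stratum`, `level`, `set`, `snp_count`,
#'   `Q`, `p_value`, `method`.
#' @export
run_set_tests <- function(gm, samples, hierarchy,
                          covariates = c("age", "institution",
                                         "ancestry_pc1"),
                          strata = NULL, method = "davies") {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(hierarchy, "pathway_hierarchy"))
  samples <- validate_samples(samples)
  if (!identical(gm$sample_ids, samples$sample_id))
    stop("genotype matrix and sample table are not aligned")
  need <- unique(unlist(c(hierarchy$pathway, hierarchy$subpathways,
                          hierarchy$genes), use.names = FALSE))
  absent <- setdiff(need, gm$snp_ids)
  if (length(absent))
    stop("hierarchy SNP(s) absent from genotype matrix: ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) " ...")
  Gall <- mean_impute(gm)
  sets <- rbind(
    data.frame(level = "pathway", set = names(hierarchy$pathway),
               stringsAsFactors = FALSE),
    data.frame(level = "subpathway", set = names(hierarchy$subpathways),
               stringsAsFactors = FALSE),
    data.frame(level = "gene", set = names(hierarchy$genes),
               stringsAsFactors = FALSE))
  set_ids <- c(hierarchy$pathway, hierarchy$subpathways, hierarchy$genes)
  run_one <- function(idx, label) {
    sam <- samples[idx, , drop = FALSE]
    cov <- .stratum_covariates(sam, covariates)
    null <- fit_null_logistic(sam, cov)
    out <- lapply(seq_len(nrow(sets)), function(i) {
      ids <- set_ids[[i]]
      if (sets$level[i] == "gene" && length(ids) < 2L)
        return(data.frame(stratum = label, level = sets$level[i],
                          set = sets$set[i], snp_count = length(ids),
                          Q = NA_real_, p_value = NA_real_,
                          method = "not_tested", stringsAsFactors = FALSE))
      res <- kernel_set_test(null, Gall[idx, ids, drop = FALSE],
                             method = method)
      data.frame(stratum = label, level = sets$level[i], set = sets$set[i],
                 snp_count = res$snp_count, Q = res$Q,
                 p_value = res$p_value, method = res$method,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  results <- run_one(seq_len(nrow(samples)), "overall")
  if (!is.null(strata)) {
    if (!strata %in% names(samples)) stop("unknown strata column: ", strata)
    for (s in sort(unique(samples[[strata]]))) {
      idx <- which(samples[[strata]] == s)
      results <- rbind(results, run_one(idx, as.character(s)))
    }
  }
  rownames(results) <- NULL
  results
}
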