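#' Code genotype calls for single-SNP logistic models
#'
#' Codominant coding yields two indicator columns (heterozygote and rare
#' homozygote, versus the common-homozygote reference); log-additive coding
#' yields the single 0/1/2 allele-count trend column.
#'
#' @param calls Vector of 0/1/2/NA minor-allele counts.
#' @param coding `"codominant"` or `"log-additive"`.
#' @return Numeric matrix with one row per call (NA rows propagate NA).
#' @export
code_genotypes <- function(calls, coding = c("codominant", "log-additive")) {
  coding <- match.arg(coding)
  if (any(!is.na(calls) & !(calls %in% c(0, 1, 2))))
    stop("calls must be 0, 1, 2 or NA")
  if (coding == "codominant")
    cbind(het = as.numeric(calls == 1), hom = as.numeric(calls == 2))
  else
    cbind(trend = as.numeric(calls))
}

# contrast definedness from the status x genotype table (2 x 3, counts)
# het/hom: all four cells of status x {ref, that genotype} non-zero.
# trend: after dropping genotype levels absent from the whole stratum, at
# least two levels remain and every remaining status x level cell is non-zero.
.contrast_defined <- function(status, calls) {
  tab <- matrix(0, 2, 3)
  for (g in 0:2) for (s in 0:1)
    tab[s + 1, g + 1] <- sum(status == s & calls == g, na.rm = TRUE)
  het <- all(tab[, c(1, 2)] > 0)
  hom <- all(tab[, c(1, 3)] > 0)
  present <- colSums(tab) > 0
  trend <- sum(present) >= 2 && all(tab[, present] > 0)
  c(het = het, hom = hom, trend = trend)
}

#' Single-SNP logistic association
#'
#' Unconditional multivariate logistic regression of case status on one SNP
#' (codominant or log-additive coding) adjusted for covariates, with Wald
#' odds ratios, 95% confidence intervals and two-sided p-values. Contrasts
#' whose status-by-genotype table has an empty cell are flagged undefined and
#' carry no numbers. Missing genotypes are dropped per SNP (complete case).
#'
#' @param gm A `genotype_matrix`.
#' @param samples Aligned sample table.
#' @param snp_id SNP to test.
#' @param coding `"codominant"` or `"log-additive"`.
#' @param covariates Adjustment covariates (default age, institution,
#'   ancestry_pc1); constants within the analysis subset are dropped.
#' @param strata Optional column name; adds per-stratum fits to the overall
#'   one.
#' @return Data frame with one row per contrast: `snp_id`, `stratum`,
#'   `coding`, `contrast`, `n`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `defined`, `note`.
#' @export
assoc_single_snp <- function(gm, samples, snp_id,
                             coding = c("codominant", "log-additive"),
                             covariates = c("age", "institution",
                                            "ancestry_pc1"),
                             strata = NULL) {
  coding <- match.arg(coding)
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- validate_samples(samples)
  if (!identical(gm$sample_ids, samples$sample_id))
    stop("genotype matrix and sample table are not aligned")
  if (!snp_id %in% gm$snp_ids) stop("unknown SNP id: ", snp_id)
  calls_all <- gm$calls[, snp_id]
  fit_one <- function(idx, label) {
    calls <- calls_all[idx]
    sam <- samples[idx, , drop = FALSE]
    cc <- !is.na(calls)
    calls <- calls[cc]; sam <- sam[cc, , drop = FALSE]
    n <- length(calls)
    contrasts <- if (coding == "codominant") c("het", "hom") else "trend"
    blank <- function(contrast, note) {
      data.frame(snp_id = snp_id, stratum = label, coding = coding,
                 contrast = contrast, n = n, or = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                 defined = FALSE, note = note, stringsAsFactors = FALSE)
    }
    if (n == 0L)
      return(do.call(rbind, lapply(contrasts, blank, note = "no data")))
    def <- .contrast_defined(sam$status, calls)
    wanted <- def[contrasts]
    if (!any(wanted))
      return(do.call(rbind,
                     lapply(contrasts, blank,
                            note = "empty status x genotype cell")))
    X <- code_genotypes(calls, coding)
    use <- colnames(X)[def[colnames(X)]]
    dat <- data.frame(status = sam$status, X[, use, drop = FALSE])
    cov <- .stratum_covariates(sam, intersect(covariates, names(sam)))
    for (v in cov) dat[[v]] <- sam[[v]]
    fit <- tryCatch(
      stats::glm(status ~ ., family = stats::binomial(), data = dat,
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
      error = function(e) NULL)
    sep <- is.null(fit) || !fit$converged ||
      any(abs(stats::coef(fit)[use]) > 15, na.rm = TRUE)
    rows <- lapply(contrasts, function(ct) {
      if (!def[ct]) return(blank(ct, "empty status x genotype cell"))
      if (sep) return(blank(ct, "separation or non-convergence"))
      co <- summary(fit)$coefficients
      if (!ct %in% rownames(co)) return(blank(ct, "dropped from fit"))
      b <- co[ct, "Estimate"]; se <- co[ct, "Std. Error"]
      data.frame(snp_id = snp_id, stratum = label, coding = coding,
                 contrast = ct, n = n, or = exp(b),
                 ci_low = exp(b - 1.959964 * se),
                 ci_high = exp(b + 1.959964 * se),
                 p_value = 2 * stats::pnorm(-abs(b / se)),
                 defined = TRUE, note = "", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- fit_one(seq_along(calls_all), "overall")
  if (!is.null(strata)) {
    if (!strata %in% names(samples)) stop("unknown strata column: ", strata)
    for (s in sort(unique(samples[[strata]])))
      out <- rbind(out, fit_one(which(samples[[strata]] == s),
                                as.character(s)))
  }
  rownames(out) <- NULL
  out
}

#' Per-SNP association across all SNPs of an annotation
#'
#' Convenience wrapper running [assoc_single_snp()] for both codings across
#' the pathway SNPs (AIMs excluded).
#'
#' @inheritParams assoc_single_snp
#' @param annotation Annotation data frame; only non-AIM SNPs present in `gm`
#'   are tested.
#' @return Row-bound result data frame with `gene` and `chrom` merged in.
#' @export
assoc_all_snps <- function(gm, samples, annotation,
                           covariates = c("age", "institution",
                                          "ancestry_pc1"),
                           strata = NULL) {
  snp <- annotation[!annotation$is_aim & annotation$snp_id %in% gm$snp_ids, ,
                    drop = FALSE]
  res <- lapply(snp$snp_id, function(id) {
    rbind(assoc_single_snp(gm, samples, id, "codominant", covariates, strata),
          assoc_single_snp(gm, samples, id, "log-additive", covariates,
                           strata))
  })
  out <- do.call(rbind, res)
  i <- match(out$snp_id, snp$snp_id)
  out$gene <- snp$gene[i]
  out$chrom <- snp$chrom[i]
  out
}
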