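#' Rank-1 kernel (score) tests for every SNP
#'
#' The kernel test of a single-SNP set reduces to the 1-df score test: with
#' `K = g g'`, `Q = (g'r)^2` and the single mixture weight is
#' `lambda = g' P0 g`, so `p = P(chi^2_1 > Q / lambda)`. Computed here for
#' all SNP columns at once; used for the SNP level of the permutation
#' family-wise error procedure.
#'
#' @param null A `null_model`.
#' @param G Complete genotype matrix (samples x SNPs) aligned to the model.
#' @return Data frame `snp_id`, `Q`, `lambda`, `p_value`.
#' @export
single_snp_score_tests <- function(null, G) {
  stopifnot(inherits(null, "null_model"))
  G <- as.matrix(G)
  v <- null$weights
  X <- null$design
  r <- null$y - null$fitted
  Q <- drop(crossprod(G, r))^2
  GtVX <- crossprod(G * v, X)
  XtVX <- crossprod(X, X * v)
  lam <- colSums(G^2 * v) - rowSums((GtVX %*% solve(XtVX)) * GtVX)
  lam[lam < 0] <- 0
  p <- ifelse(lam > 0,
              stats::pchisq(Q / pmax(lam, .Machine$double.eps), df = 1,
                            lower.tail = FALSE),
              1)
  data.frame(snp_id = colnames(G), Q = Q, lambda = lam, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# observed p-values for one grouping level on a given sample table
.level_pvalues <- function(level, G, samples, hierarchy, covariates,
                           method) {
  cov <- .stratum_covariates(samples, covariates)
  null <- fit_null_logistic(samples, cov)
  if (level == "snp") {
    res <- single_snp_score_tests(null, G)
    return(stats::setNames(res$p_value, res$snp_id))
  }
  sets <- switch(level, pathway = hierarchy$pathway,
                 subpathway = hierarchy$subpathways,
                 gene = hierarchy$genes,
                 stop("unknown level: ", level))
  if (level == "gene") sets <- sets[lengths(sets) >= 2L]
  vapply(sets, function(ids)
    kernel_set_test(null, G[, ids, drop = FALSE], method = method)$p_value,
    numeric(1))
}

#' Permutation min-P family-wise error adjustment at every grouping level
#'
#' For each requested level (pathway, sub-pathway, gene, SNP) the observed
#' p-values are compared to the permutation distribution of the level's
#' minimum p-value: case/control labels are permuted (stratified by ethnicity
#' and institution by default), the null model is refitted and every test at
#' the level recomputed, `B` times.
#'
#' @param gm QC'd `genotype_matrix` (mean-imputed internally).
#' @param samples Aligned sample table (with `ancestry_pc1` if used).
#' @param hierarchy A `pathway_hierarchy`.
#' @param B Number of permutations (study default 1000).
#' @param seed Integer seed; per-level streams are derived from it.
#' @param levels Which grouping levels to adjust.
#' @param covariates Null-model covariates.
#' @param scheme Permutation scheme, see [permute_phenotype()].
#' @param method Set-test p-value engine, see [quadform_pvalue()].
#' @return Named list of `permutation_summary` objects, one per level.
#' @export
fwer_all_levels <- function(gm, samples, hierarchy, B = 1000, seed,
                            levels = c("pathway", "subpathway", "gene",
                                       "snp"),
                            covariates = c("age", "institution",
                                           "ancestry_pc1"),
                            scheme = "stratified", method = "davies") {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- validate_samples(samples)
  snp_ids <- hierarchy$pathway[[1]]
  G <- mean_impute(subset_genotypes(gm, snps = snp_ids))
  out <- list()
  for (k in seq_along(levels)) {
    lev <- levels[k]
    observed <- .level_pvalues(lev, G, samples, hierarchy, covariates,
                               method)
    cb <- function(b) {
      perm <- permute_phenotype(samples, scheme = scheme)
      .level_pvalues(lev, G, perm, hierarchy, covariates, method)
    }
    out[[lev]] <- minp_fwer(observed, B, cb, seed = seed + k - 1L)
  }
  out
}

#' Run the full association pipeline
#'
#' QC, ancestry PCA on the AIMs, cohort description, kernel set tests at
#' pathway / sub-pathway / gene level (overall and per ethnicity), per-SNP
#' codominant and log-additive logistic models, a reporting table restricted
#' to SNPs with any contrast p-value under `snp_p_threshold`, permutation
#' min-P family-wise error adjustment per level, and a JSON-able run
#' manifest. Deterministic given `seed`.
#'
#' @param gm A `genotype_matrix` covering pathway SNPs and AIMs.
#' @param samples Sample table.
#' @param annotation Annotation covering the genotyped SNPs (default the
#'   packaged fixture).
#' @param covariates Adjustment covariates for all association models.
#' @param strata Stratification column for the per-group runs (default
#'   ethnicity; `NULL` disables).
#' @param B Permutations for the FWER step (study default 1000; set 0 to
#'   skip).
#' @param seed Mandatory integer seed.
#' @param snp_p_threshold Reporting threshold for the SNP table (default
#'   0.01).
#' @param fwer_levels Levels to adjust, see [fwer_all_levels()].
#' @param fwer_method P-value engine used inside the permutation loop (both
#'   observed and permuted p-values of the adjustment use it, keeping the
#'   family comparable); `"liu"` is markedly faster for large permutation
#'   counts.
#' @param scheme Permutation scheme.
#' @param outdir Optional directory; when given, tables are written as TSV
#'   and the manifest as JSON.
#' @return List with `qc`, `ancestry`, `samples` (post-QC, with
#'   `ancestry_pc1`), `descriptives`, `set_tests`, `snp_results`,
#'   `snp_table`, `fwer`, `manifest`.
#' @export
run_pipeline <- function(gm, samples, annotation = pathway_annotation(),
                         covariates = c("age", "institution",
                                        "ancestry_pc1"),
                         strata = "ethnicity", B = 1000, seed,
                         snp_p_threshold = 0.01,
                         fwer_levels = c("pathway", "subpathway", "gene",
                                         "snp"),
                         fwer_method = "davies",
                         scheme = "stratified", outdir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  qc <- apply_qc(gm, samples)
  gmq <- qc$genotypes
  sam <- qc$samples
  annot <- annotation[annotation$snp_id %in% gmq$snp_ids, , drop = FALSE]
  aim_ids <- annot$snp_id[annot$is_aim]
  if (length(aim_ids) < 2L)
    stop("fewer than 2 ancestry-informative markers survive QC")
  scores <- pca_ancestry(subset_genotypes(gmq, snps = aim_ids), k = 2)
  sam <- add_ancestry(sam, scores)
  hierarchy <- build_hierarchy(annot)
  desc <- cohort_summary(sam)
  set_tests <- run_set_tests(gmq, sam, hierarchy, covariates,
                             strata = strata)
  snp_results <- assoc_all_snps(gmq, sam, annot, covariates,
                                strata = strata)
  hit <- unique(snp_results$snp_id[
    snp_results$stratum == "overall" & snp_results$defined &
      !is.na(snp_results$p_value) &
      snp_results$p_value < snp_p_threshold])
  snp_table <- snp_results[snp_results$snp_id %in% hit, , drop = FALSE]
  fwer <- if (B > 0)
    fwer_all_levels(gmq, sam, hierarchy, B = B, seed = seed,
                    levels = fwer_levels, covariates = covariates,
                    scheme = scheme, method = fwer_method)
  else NULL
  manifest <- list(
    package = "snpsetkm",
    version = as.character(utils::packageVersion("snpsetkm")),
    seed = seed, B = B, covariates = covariates, strata = strata,
    scheme = scheme, snp_p_threshold = snp_p_threshold,
    n_samples = nrow(sam), n_snps = sum(!annot$is_aim),
    n_aims = length(aim_ids),
    snps_excluded = nrow(qc$snp_log),
    samples_excluded = nrow(qc$sample_log))
  out <- list(qc = qc[c("sample_log", "snp_log")], ancestry = scores,
              samples = sam, descriptives = desc, set_tests = set_tests,
              snp_results = snp_results, snp_table = snp_table,
              fwer = fwer, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Write pipeline outputs as TSV tables plus a JSON manifest
#'
#' @param result Return value of [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(result$set_tests[, c("stratum", "level", "set", "snp_count", "Q",
                         "p_value", "method")], "set_tests.tsv")
  w(result$snp_table, "snp_table.tsv")
  w(result$snp_results, "snp_results.tsv")
  w(result$qc$snp_log, "qc_snp_exclusions.tsv")
  w(result$qc$sample_log, "qc_sample_exclusions.tsv")
  w(as.data.frame(result$ancestry), "ancestry_scores.tsv")
  w(result$descriptives$quantitative, "descriptives_quantitative.tsv")
  w(result$descriptives$categorical, "descriptives_categorical.tsv")
  if (!is.null(result$fwer)) {
    fw <- do.call(rbind, lapply(names(result$fwer), function(lev) {
      s <- result$fwer[[lev]]
      data.frame(level = lev, test = names(s$observed),
                 p_observed = s$observed, p_adjusted = s$adjusted,
                 B = s$B, seed = s$seed, stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
    w(fw, "fwer.tsv")
  }
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
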