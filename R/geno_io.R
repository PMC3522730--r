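#' Construct a genotype matrix
#'
#' A genotype matrix holds minor-allele counts (0, 1, 2 or `NA`) for a set of
#' samples (rows) and biallelic SNPs (columns). It is the `G` whose inner
#' product `G G'` defines the linear kernel used by the set tests.
#'
#' @param calls Numeric or integer matrix; entries must be 0, 1, 2 or `NA`.
#' @param sample_ids Character vector of unique sample identifiers (rows).
#' @param snp_ids Character vector of unique SNP identifiers (columns).
#' @param alleles Optional data frame with columns `minor` and `major` giving
#'   per-SNP allele symbols.
#' @return An object of class `genotype_matrix`: a list with elements `calls`
#'   (the matrix, dimnames set), `sample_ids`, `snp_ids`, `alleles`.
#' @export
genotype_matrix <- function(calls, sample_ids, snp_ids, alleles = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (nrow(calls) != length(sample_ids))
    stop("number of rows (", nrow(calls), ") does not match sample_ids (",
         length(sample_ids), ")")
  if (ncol(calls) != length(snp_ids))
    stop("number of columns (", ncol(calls), ") does not match snp_ids (",
         length(snp_ids), ")")
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype value '", calls[bad][1], "' at sample '",
         sample_ids[idx[1]], "', SNP '", snp_ids[idx[2]], "'; expected 0/1/2/NA")
  }
  if (!is.null(alleles)) {
    alleles <- as.data.frame(alleles)
    if (!all(c("minor", "major") %in% names(alleles)) ||
        nrow(alleles) != length(snp_ids))
      stop("alleles must have columns 'minor' and 'major', one row per SNP")
  }
  dimnames(calls) <- list(sample_ids, snp_ids)
  structure(list(calls = calls, sample_ids = sample_ids, snp_ids = snp_ids,
                 alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs;",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or SNP identifiers
#'
#' @param gm A `genotype_matrix`.
#' @param samples,snps Character vectors of identifiers to keep (default all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = gm$sample_ids, snps = gm$snp_ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss_s <- setdiff(samples, gm$sample_ids)
  if (length(miss_s)) stop("unknown sample ids: ", paste(miss_s, collapse = ", "))
  miss_p <- setdiff(snps, gm$snp_ids)
  if (length(miss_p)) stop("unknown SNP ids: ", paste(miss_p, collapse = ", "))
  al <- gm$alleles
  if (!is.null(al)) al <- al[match(snps, gm$snp_ids), , drop = FALSE]
  genotype_matrix(gm$calls[samples, snps, drop = FALSE], samples, snps, al)
}

# orient a count matrix so columns count the minor allele; returns list of
# matrix + logical flip indicator per column
.orient_minor <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) calls[, flip] <- 2 - calls[, flip, drop = FALSE]
  list(calls = calls, flipped = flip)
}

#' Read a genotype matrix from VCF or TSV
#'
#' Two formats are supported. `tsv`: a tab-separated table, header row of SNP
#' ids, first column the sample id, remaining cells 0/1/2/NA counts. `vcf`: a
#' VCF with GT fields; diploid genotypes, phased or unphased, are accepted and
#' ALT-allele counts are extracted. In both cases columns are re-oriented so
#' that counts refer to the minor allele, defined by observed frequency on the
#' full sample; a tie at frequency 0.5 is broken lexicographically by allele
#' symbol (VCF) or left as read (TSV, no symbols available).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "tsv") .read_genotypes_tsv(path) else .read_genotypes_vcf(path)
}

.read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("genotype TSV is empty or has no SNP columns: ", path)
  sample_ids <- tab[[1]]
  snp_ids <- colnames(tab)[-1]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  ok <- is.na(cells) | cells %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("unparsable genotype '", cells[!ok][1], "' at row ", idx[1],
         " (sample '", sample_ids[idx[1]], "'), column '", snp_ids[idx[2]],
         "'; expected 0/1/2/NA")
  }
  cells[cells == "NA"] <- NA
  calls <- matrix(as.numeric(cells), nrow = nrow(cells))
  o <- .orient_minor(calls)
  genotype_matrix(o$calls, sample_ids, snp_ids)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("VCF has no GT genotypes: ", path)
  fix <- vcfR::getFIX(v)
  snp_ids <- fix[, "ID"]
  noid <- is.na(snp_ids) | snp_ids == "."
  snp_ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    known <- !is.na(g) & g != "." & g != "./." & g != ".|."
    parts <- strsplit(g[known], "[/|]")
    out[known] <- vapply(parts, function(p) {
      if (length(p) != 2L || any(!p %in% c("0", "1")))
        stop("unsupported GT '", paste(p, collapse = "/"),
             "'; only diploid biallelic 0/1 genotypes are handled")
      sum(p == "1")
    }, numeric(1))
    out
  }
  calls <- t(apply(gt, 1, count_alt))          # SNP x sample
  calls <- t(calls)                             # sample x SNP
  sample_ids <- colnames(gt)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  f_alt <- colMeans(calls, na.rm = TRUE) / 2
  minor <- ifelse(f_alt < 0.5, alt,
                  ifelse(f_alt > 0.5, ref, pmin(ref, alt)))
  flip <- minor != alt
  flip[is.na(flip)] <- FALSE
  if (any(flip)) calls[, flip] <- 2 - calls[, flip, drop = FALSE]
  major <- ifelse(minor == alt, ref, alt)
  genotype_matrix(calls, sample_ids, snp_ids,
                  alleles = data.frame(minor = minor, major = major))
}

#' Read the sample (phenotype/covariate) table
#'
#' Expects a tab-separated file with columns `sample_id`, `status` (1 = case,
#' 0 = control), `age` (years, positive), `institution` and `ethnicity`
#' (two-group category). An `ancestry_pc1` column, if present, is kept.
#'
#' @param path Path to the TSV.
#' @return A validated data frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("cannot read sample table (",
                                           conditionMessage(e), "): ", path))
  req <- c("sample_id", "status", "age", "institution", "ethnicity")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("sample table is missing column(s) ",
         paste(missing_cols, collapse = ", "),
         "; expected schema: ", paste(req, collapse = ", "))
  if (nrow(tab) == 0L) stop("sample table is empty: ", path)
  validate_samples(tab)
}

#' Validate a sample table
#'
#' @param tab Data frame with at least `sample_id`, `status`, `age`,
#'   `institution`, `ethnicity`.
#' @return The table, with `sample_id` as character and `status` numeric.
#' @export
validate_samples <- function(tab) {
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in sample table")
  if (!all(tab$status %in% c(0, 1)))
    stop("status must be 0 (control) or 1 (case); offending values: ",
         paste(utils::head(unique(tab$status[!tab$status %in% c(0, 1)])),
               collapse = ", "))
  if (any(!is.finite(tab$age)) || any(tab$age <= 0))
    stop("age must be a positive number for every sample")
  tab
}

#' Read the SNP annotation table
#'
#' Expects a tab-separated file with columns `snp_id`, `chrom`, `pos`, `gene`,
#' `subpathway`, `is_aim`. Ancestry-informative markers (`is_aim` = 1) carry
#' empty `gene`/`subpathway`; every other SNP maps to exactly one gene and one
#' of the six sub-pathway names of the packaged hierarchy.
#'
#' @param path Path to the TSV.
#' @return A validated data frame with logical `is_aim`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = NULL)
  req <- c("snp_id", "chrom", "pos", "gene", "subpathway", "is_aim")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("annotation is missing column(s) ",
         paste(missing_cols, collapse = ", "),
         "; expected schema: ", paste(req, collapse = ", "))
  if (nrow(tab) == 0L) stop("annotation table is empty: ", path)
  tab$is_aim <- tab$is_aim %in% c(1, "1", TRUE, "TRUE")
  if (anyDuplicated(tab$snp_id)) stop("duplicate SNP ids in annotation")
  snp <- tab[!tab$is_aim, , drop = FALSE]
  bad <- !(snp$subpathway %in% subpathway_names())
  if (any(bad))
    stop("unknown sub-pathway name(s): ",
         paste(unique(snp$subpathway[bad]), collapse = "; "),
         "; allowed: ", paste(subpathway_names(), collapse = "; "))
  if (any(snp$gene == "" | is.na(snp$gene)))
    stop("non-AIM SNPs must carry a gene symbol")
  tab
}

#' The closed six-name sub-pathway vocabulary
#' @return Character vector of the six sub-pathway names.
#' @export
subpathway_names <- function() {
  c("cytokine signaling", "eicosanoid signaling",
    "extracellular pattern recognition", "intracellular antiviral molecules",
    "NFKB signaling", "selenoproteins")
}

#' Minor allele frequency of one SNP
#'
#' `min(f, 1 - f)` where `f` is the counted-allele frequency
#' `sum(calls) / (2 * n_nonmissing)`. Invariant under swapping which allele is
#' counted.
#'
#' @param calls Vector of 0/1/2/NA calls for one SNP.
#' @return Frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(calls) {
  n <- sum(!is.na(calls))
  if (n == 0L) stop("minor allele frequency undefined: all calls missing")
  f <- sum(calls, na.rm = TRUE) / (2 * n)
  min(f, 1 - f)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against the proportions `p^2, 2pq, q^2` expected at the observed allele
#' frequency; upper-tail p-value. A monomorphic SNP returns statistic 0,
#' p-value 1.
#'
#' @param counts Length-3 vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return List with `statistic` and `p_value`.
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3L || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be three non-negative integers (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  if (n == 0L) stop("no genotypes: total count is zero")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    return(list(statistic = 0, p_value = 1))
  expected <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# genotype counts (n0, n1, n2) for a call vector
.geno_counts <- function(calls) {
  c(sum(calls == 0, na.rm = TRUE), sum(calls == 1, na.rm = TRUE),
    sum(calls == 2, na.rm = TRUE))
}

#' Sample-level quality control
#'
#' Removes samples whose genotype call rate is below 0.90 (strict inequality,
#' as for all QC thresholds in this package).
#'
#' @param gm A `genotype_matrix`.
#' @param min_call_rate Threshold, default 0.90.
#' @return List with `genotypes` (kept matrix) and `log` (data frame
#'   `id`, `reason` for excluded samples).
#' @export
qc_samples <- function(gm, min_call_rate = 0.90) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cr <- rowMeans(!is.na(gm$calls))
  drop <- cr < min_call_rate
  if (all(drop)) stop("sample QC removed every sample (call rates all below ",
                      min_call_rate, ")")
  log <- data.frame(id = gm$sample_ids[drop],
                    reason = sprintf("call_rate %.4f < %.2f", cr[drop],
                                     min_call_rate),
                    stringsAsFactors = FALSE)
  list(genotypes = subset_genotypes(gm, samples = gm$sample_ids[!drop]),
       log = log)
}

#' SNP-level quality control
#'
#' A SNP is excluded if its call rate is below `min_call_rate`, or it deviates
#' from Hardy-Weinberg proportions at `hwe_alpha` in *both* ethnicity groups,
#' or its minor allele frequency is below `min_maf` in *both* groups. All
#' thresholds are strict. If only one ethnicity group is present the
#' both-group rules are evaluated on that single group (and this is logged).
#'
#' @param gm A `genotype_matrix`.
#' @param samples Sample table aligned by `sample_id` (must cover all samples
#'   in `gm`); supplies the `ethnicity` grouping.
#' @param min_call_rate,hwe_alpha,min_maf Thresholds (defaults 0.90, 0.01,
#'   0.01).
#' @return List with `genotypes` (kept matrix) and `log` (data frame
#'   `id`, `reason` for excluded SNPs).
#' @export
qc_snps <- function(gm, samples, min_call_rate = 0.90, hwe_alpha = 0.01,
                    min_maf = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- validate_samples(samples)
  if (!all(gm$sample_ids %in% samples$sample_id))
    stop("sample table does not cover all genotyped samples")
  eth <- samples$ethnicity[match(gm$sample_ids, samples$sample_id)]
  groups <- split(seq_along(eth), eth)
  if (length(groups) == 1L)
    message("only one ethnicity group present; group-wise QC rules ",
            "evaluated on that single group")
  reasons <- character(0)
  ids <- character(0)
  for (j in seq_along(gm$snp_ids)) {
    col <- gm$calls[, j]
    cr <- mean(!is.na(col))
    why <- character(0)
    if (cr < min_call_rate)
      why <- c(why, sprintf("call_rate %.4f < %.2f", cr, min_call_rate))
    grp_cols <- lapply(groups, function(i) col[i])
    grp_cols <- grp_cols[vapply(grp_cols, function(x) any(!is.na(x)),
                                logical(1))]
    if (length(grp_cols)) {
      hwe_p <- vapply(grp_cols,
                      function(x) hwe_chisq(.geno_counts(x))$p_value,
                      numeric(1))
      if (all(hwe_p < hwe_alpha))
        why <- c(why, sprintf("hwe_p < %.2g in all groups (%s)", hwe_alpha,
                              paste(signif(hwe_p, 3), collapse = ", ")))
      mafs <- vapply(grp_cols, compute_maf, numeric(1))
      if (all(mafs < min_maf))
        why <- c(why, sprintf("maf < %.2g in all groups (%s)", min_maf,
                              paste(signif(mafs, 3), collapse = ", ")))
    }
    if (length(why)) {
      ids <- c(ids, gm$snp_ids[j])
      reasons <- c(reasons, paste(why, collapse = "; "))
    }
  }
  keep <- setdiff(gm$snp_ids, ids)
  if (!length(keep)) stop("SNP QC removed every SNP")
  list(genotypes = subset_genotypes(gm, snps = keep),
       log = data.frame(id = ids, reason = reasons, stringsAsFactors = FALSE))
}

#' Full quality control pass
#'
#' Sample call-rate filter first, then SNP filters computed on the retained
#' samples (one pass).
#'
#' @param gm A `genotype_matrix`.
#' @param samples Sample table.
#' @param ... Passed to [qc_snps()].
#' @return List with `genotypes`, `samples` (restricted to kept samples),
#'   `sample_log`, `snp_log`.
#' @export
apply_qc <- function(gm, samples, ...) {
  samples <- validate_samples(samples)
  s <- qc_samples(gm)
  p <- qc_snps(s$genotypes, samples, ...)
  kept <- p$genotypes$sample_ids
  list(genotypes = p$genotypes,
       samples = samples[match(kept, samples$sample_id), , drop = FALSE],
       sample_log = s$log, snp_log = p$log)
}

#' Write a genotype matrix in the package TSV dialect
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tab <- data.frame(sample_id = gm$sample_ids, gm$calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
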