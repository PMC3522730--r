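#' Standardize genotypes for principal component analysis
#'
#' Per SNP: missing calls are imputed at the column mean, counts are centered
#' at `2*p` and scaled by `sqrt(2*p*(1-p))` where `p` is the observed allele
#' frequency of the counted allele (the EIGENSTRAT convention, appropriate
#' for binomially sampled alleles). Monomorphic SNPs carry no information and
#' are dropped; their ids are returned.
#'
#' @param gm A `genotype_matrix`.
#' @return List with `z` (standardized numeric matrix, samples x SNPs) and
#'   `dropped` (ids of monomorphic SNPs).
#' @export
standardize_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$calls) < 2L) stop("need at least 2 samples to standardize")
  x <- gm$calls
  p <- colMeans(x, na.rm = TRUE) / 2
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (all(mono)) stop("all SNPs are monomorphic; nothing to standardize")
  x <- x[, !mono, drop = FALSE]
  p <- p[!mono]
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- 2 * p[j]
  }
  z <- sweep(x, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  list(z = z, dropped = gm$snp_ids[mono])
}

#' Ancestry principal components from ancestry-informative markers
#'
#' Computes principal component scores of a standardized AIM matrix via the
#' singular value decomposition. Scores are the left singular vectors scaled
#' by their singular values (classical PC scores of the sample covariance);
#' each component's sign is fixed so that its largest-magnitude SNP loading
#' is positive. The first component is the genetic-ancestry estimate used as
#' an adjustment covariate downstream.
#'
#' @param z Standardized matrix from [standardize_genotypes()] (`$z`), or a
#'   `genotype_matrix` (standardized internally).
#' @param k Number of components to return (default 2); truncated with a
#'   warning if it exceeds the matrix rank.
#' @return An object of class `ancestry_scores`: data frame with `sample_id`
#'   and `PC1..PCk`; attributes `explained_variance` (per component, fraction
#'   of total) and `loadings`.
#' @export
pca_ancestry <- function(z, k = 2) {
  if (inherits(z, "genotype_matrix")) z <- standardize_genotypes(z)$z
  if (ncol(z) < 2L) stop("need at least 2 polymorphic markers for PCA")
  ids <- rownames(z)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(z)))
  zc <- sweep(z, 2, colMeans(z))        # center over samples
  sv <- svd(zc)
  tol <- max(dim(zc)) * .Machine$double.eps * max(sv$d)
  rank <- sum(sv$d > max(tol, 1e-12))
  if (rank == 0L) stop("degenerate input: all samples identical")
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank, "; truncating")
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores <- sweep(scores, 2, colMeans(scores))  # numerically exact centering
  out <- data.frame(sample_id = ids, scores, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("PC", seq_len(k)))
  attr(out, "explained_variance") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  attr(out, "loadings") <- load
  class(out) <- c("ancestry_scores", "data.frame")
  out
}

#' Attach the first ancestry principal component to a sample table
#'
#' @param samples Sample table.
#' @param scores `ancestry_scores` from [pca_ancestry()].
#' @return The sample table with an `ancestry_pc1` column.
#' @export
add_ancestry <- function(samples, scores) {
  samples <- validate_samples(samples)
  i <- match(samples$sample_id, scores$sample_id)
  if (anyNA(i)) stop("ancestry scores missing for sample(s): ",
                     paste(samples$sample_id[is.na(i)], collapse = ", "))
  samples$ancestry_pc1 <- scores$PC1[i]
  samples
}
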