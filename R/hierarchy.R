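#' Build the pathway -> sub-pathway -> gene hierarchy from an annotation
#'
#' The hierarchy defines the tested SNP sets: one whole-pathway set, one set
#' per sub-pathway, one set per gene. Gene sets partition their sub-pathway
#' set and sub-pathway sets partition the pathway set; this is checked.
#' Ancestry-informative markers are excluded from all sets.
#'
#' @param annotation Annotation data frame as returned by [read_annotation()].
#' @param pathway_name Label for the whole-pathway set.
#' @return An object of class `pathway_hierarchy`: a list with `pathway`
#'   (named list of one SNP-id vector), `subpathways`, `genes` (named lists of
#'   SNP-id vectors), and `gene_subpathway` (named character vector).
#' @export
build_hierarchy <- function(annotation,
                            pathway_name = "innate immunity and inflammation") {
  snp <- annotation[!annotation$is_aim, , drop = FALSE]
  if (nrow(snp) == 0L) stop("annotation contains no pathway SNPs")
  genes <- split(snp$snp_id, snp$gene)
  subs <- split(snp$snp_id, snp$subpathway)
  gene_sub <- tapply(snp$subpathway, snp$gene, function(x) unique(x))
  multi <- names(gene_sub)[lengths(gene_sub) > 1L]
  if (length(multi))
    stop("gene(s) mapped to more than one sub-pathway: ",
         paste(multi, collapse = ", "))
  gene_sub <- vapply(gene_sub, identity, character(1))
  all_ids <- snp$snp_id
  stopifnot(identical(sort(unlist(genes, use.names = FALSE)), sort(all_ids)),
            identical(sort(unlist(subs, use.names = FALSE)), sort(all_ids)))
  h <- list(pathway = stats::setNames(list(all_ids), pathway_name),
            subpathways = subs, genes = genes, gene_subpathway = gene_sub)
  class(h) <- "pathway_hierarchy"
  h
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat("pathway_hierarchy:", length(x$pathway[[1]]), "SNPs,",
      length(x$subpathways), "sub-pathways,", length(x$genes), "genes\n")
  invisible(x)
}

#' SNP-set sizes of a hierarchy
#' @param h A `pathway_hierarchy`.
#' @return List of named integer vectors `pathway`, `subpathways`, `genes`.
#' @export
hierarchy_sizes <- function(h) {
  stopifnot(inherits(h, "pathway_hierarchy"))
  list(pathway = lengths(h$pathway), subpathways = lengths(h$subpathways),
       genes = lengths(h$genes))
}

#' Packaged synthetic pathway annotation
#'
#' Loads the annotation fixture shipped with the package: a synthetic SNP map
#' reproducing the study design of 320 tag SNPs in 46 innate-immunity and
#' inflammation genes grouped into 6 sub-pathways, plus 39
#' ancestry-informative markers. SNP identifiers and positions are synthetic;
#' gene symbols, chromosomes, sub-pathway membership and per-gene SNP counts
#' follow the published design.
#'
#' @return Annotation data frame (see [read_annotation()]).
#' @export
pathway_annotation <- function() {
  path <- system.file("extdata", "synthetic_annotation.tsv",
                      package = "snpsetkm", mustWork = TRUE)
  read_annotation(path)
}
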