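#!/usr/bin/env Rscript

# Quality control and genetic-ancestry estimation. Samples with call rate
# below 0.90 are dropped; SNPs are dropped for call rate < 0.90, or
# Hardy-Weinberg P < 0.01 in both ethnicity groups, or MAF < 0.01 in both
# groups. The first principal component of the 39 ancestry-informative
# markers becomes the ancestry adjustment covariate.

suppressPackageStartupMessages(library(snpsetkm))

datadir <- "results/data"
outdir <- "results"
gm <- read_genotypes(file.path(datadir, "genotypes.tsv"))
samples <- read_samples(file.path(datadir, "samples.tsv"))
annot <- read_annotation(file.path(datadir, "annotation.tsv"))

qc <- apply_qc(gm, samples)
message(nrow(qc$sample_log), " samples and ", nrow(qc$snp_log),
        " SNPs excluded by QC; ", length(qc$genotypes$snp_ids),
        " SNPs retained")
write.table(qc$snp_log, file.path(outdir, "qc_snp_exclusions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(qc$sample_log, file.path(outdir, "qc_sample_exclusions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

aims <- intersect(annot$snp_id[annot$is_aim], qc$genotypes$snp_ids)
scores <- pca_ancestry(subset_genotypes(qc$genotypes, snps = aims), k = 2)
ev <- attr(scores, "explained_variance")
grp <- qc$samples$ethnicity[match(scores$sample_id, qc$samples$sample_id)]
message(sprintf("AIM PCA: PC1 explains %.1f%% of variance; |cor(PC1, ethnicity)| = %.2f",
                100 * ev[1], abs(cor(scores$PC1, grp == "group2"))))
write.table(as.data.frame(scores), file.path(outdir, "ancestry_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

post <- add_ancestry(qc$samples, scores)
write.table(post, file.path(outdir, "samples_postqc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_genotypes(qc$genotypes, file.path(outdir, "genotypes_postqc.tsv"))
message("post-QC tables written under ", outdir)
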