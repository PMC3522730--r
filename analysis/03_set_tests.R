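#!/usr/bin/env Rscript

# Kernel-machine set tests at pathway, sub-pathway and gene level, adjusted
# for age, institution and ancestry PC1, overall and stratified by
# ethnicity. P-values come from the exact characteristic-function inversion
# of the score statistic's chi-square mixture.

suppressPackageStartupMessages(library(snpsetkm))

gm <- read_genotypes("results/genotypes_postqc.tsv")
samples <- read_samples("results/samples_postqc.tsv")
annot <- read_annotation("results/data/annotation.tsv")
annot <- annot[annot$snp_id %in% gm$snp_ids, ]
h <- build_hierarchy(annot[!annot$is_aim, ])

res <- run_set_tests(gm, samples, h, strata = "ethnicity")
write.table(res[, c("stratum", "level", "set", "snp_count", "Q", "p_value",
                    "method")],
            "results/set_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ov <- res[res$stratum == "overall", ]
message(sprintf("whole pathway (%d SNPs): p = %.3f",
                ov$snp_count[ov$level == "pathway"],
                ov$p_value[ov$level == "pathway"]))
sp <- ov[ov$level == "subpathway", ]
message("sub-pathway p-values: ",
        paste(sprintf("%s %.2f", sp$set, sp$p_value), collapse = "; "))
gene <- ov[ov$level == "gene" & ov$method != "not_tested", ]
message(sum(gene$p_value < 0.05), " of ", nrow(gene),
        " testable genes below 0.05 (", sum(ov$method == "not_tested"),
        " single-SNP genes not tested)")
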