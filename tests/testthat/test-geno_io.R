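test_that("TSV genotype round trip preserves calls and missingness", {
  tc <- make_test_cohort(n = 3, p = 2, seed = 5, missing = 0)
  gm <- tc$gm
  gm$calls[2, 1] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  back <- read_genotypes(path)
  expect_identical(back$sample_ids, gm$sample_ids)
  expect_identical(back$snp_ids, gm$snp_ids)
  expect_equal(sum(is.na(back$calls)), 1L)
  # re-orientation: columns read back always count the minor allele
  expect_true(all(colMeans(back$calls, na.rm = TRUE) / 2 <= 0.5))
})

test_that("invalid TSV entries and duplicate ids are rejected with location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsnpA\tsnpB", "s1\t0\t1", "s2\t3\t2"), path)
  expect_error(read_genotypes(path), "3.*s2.*snpA|snpA.*s2")
  writeLines(c("sample_id\tsnpA", "s1\t0", "s1\t1"), path)
  expect_error(read_genotypes(path), "duplicate")
})

test_that("VCF genotypes are parsed as ALT counts and oriented to the minor allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    "1\t100\trsA\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "1\t200\trsB\tC\tT\t.\t.\t.\tGT\t1|1\t1/1\t0/1\t1/1",
    "1\t300\trsC\tT\tC\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t1/0"), path)
  gm <- read_genotypes(path)
  # ALT minor: counts are ALT counts as read
  expect_equal(unname(gm$calls[, "rsA"]), c(0, 1, 2, 0))
  # ALT frequency 7/8 > 0.5: counts flip to the REF (minor) allele
  expect_equal(unname(gm$calls[, "rsB"]), c(0, 0, 1, 0))
  expect_equal(gm$alleles$minor[2], "C")
  # exact 0.5 tie broken lexicographically: "C" (ALT) is the minor allele
  expect_equal(unname(gm$calls[, "rsC"]), c(0, 1, 2, 1))
  expect_equal(gm$alleles$minor[3], "C")
})

test_that("sample and annotation readers validate their schema", {
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstatus\tage\tinstitution\tethnicity",
               "s1\t2\t60\ta\te1"), sp)
  expect_error(read_samples(sp), "status")
  writeLines(c("sample_id\tstatus\tage", "s1\t1\t60"), sp)
  expect_error(read_samples(sp), "institution")
  writeLines("sample_id\tstatus\tage\tinstitution\tethnicity", sp)
  expect_error(read_samples(sp), "empty")
  ap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos\tgene\tsubpathway\tis_aim",
               "s1\t1\t100\tGENE\tnot a pathway\t0"), ap)
  expect_error(read_annotation(ap), "sub-pathway")
})

test_that("packaged annotation reproduces the design counts", {
  a <- pathway_annotation()
  expect_equal(sum(!a$is_aim), 320)
  expect_equal(sum(a$is_aim), 39)
  h <- build_hierarchy(a)
  sz <- hierarchy_sizes(h)
  expect_equal(length(h$genes), 46)
  expect_equal(unname(sz$pathway), 320)
  expect_equal(sz$subpathways[["cytokine signaling"]], 179)
  expect_equal(sz$subpathways[["extracellular pattern recognition"]], 56)
  expect_equal(sz$subpathways[["intracellular antiviral molecules"]], 40)
  expect_equal(sz$subpathways[["NFKB signaling"]], 27)
  expect_equal(sz$subpathways[["selenoproteins"]], 9)
  expect_equal(sz$subpathways[["eicosanoid signaling"]], 9)
  # gene sets partition sub-pathway sets
  expect_setequal(unlist(h$genes, use.names = FALSE), h$pathway[[1]])
})

test_that("minor allele frequency follows the counting definition", {
  expect_equal(compute_maf(c(0, 1, 2, 2)), 0.375)
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(0, 1, NA)), 0.25)
  expect_error(compute_maf(c(NA, NA)), "missing")
  # invariance under swapping which allele is counted
  set.seed(2)
  for (i in 1:20) {
    x <- rbinom(30, 2, runif(1, 0.05, 0.95))
    expect_equal(compute_maf(x), compute_maf(2 - x))
  }
})

test_that("Hardy-Weinberg chi-square matches the expected-count oracle", {
  expect_equal(hwe_chisq(c(25, 50, 25)),
               list(statistic = 0, p_value = 1))
  r <- hwe_chisq(c(50, 0, 50))
  expect_equal(r$statistic, 100)
  expect_equal(r$p_value, pchisq(100, 1, lower.tail = FALSE))
  o <- oracle_hwe(90, 40, 10)
  r <- hwe_chisq(c(90, 40, 10))
  expect_equal(r$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-12)
  # monomorphic: no division by zero
  expect_equal(hwe_chisq(c(40, 0, 0)), list(statistic = 0, p_value = 1))
})

test_that("QC removes exactly the rule violators, with reasons, idempotently", {
  fx <- simulate_qc_fixture(seed = 11)
  expect_equal(ncol(fx$genotypes$calls), 330)
  res <- qc_snps(fx$genotypes, fx$samples)
  expect_equal(length(res$genotypes$snp_ids), 320)
  expect_setequal(res$log$id, fx$planted$snp_id)
  # exclusion log + kept = input, per axis
  expect_equal(nrow(res$log) + length(res$genotypes$snp_ids),
               length(fx$genotypes$snp_ids))
  # reasons match the planted violation type
  key <- c(call_rate = "call_rate", maf = "maf", hwe = "hwe")
  for (i in seq_len(nrow(fx$planted)))
    expect_match(res$log$reason[res$log$id == fx$planted$snp_id[i]],
                 key[[fx$planted$type[i]]])
  # idempotence
  res2 <- qc_snps(res$genotypes, fx$samples)
  expect_equal(nrow(res2$log), 0)
  expect_identical(res2$genotypes$snp_ids, res$genotypes$snp_ids)
})

test_that("group rules require violation in both ethnicity groups", {
  n <- 200
  eth <- rep(c("group1", "group2"), each = n / 2)
  # MAF 0.005 in group1 (one het), 0.20 in group2: must be kept
  col_keep <- c(c(1, rep(0, n / 2 - 1)), rbinom(n / 2, 2, 0.20))
  # MAF below 0.01 in both groups: removed
  col_drop <- c(c(1, rep(0, n / 2 - 1)), c(1, rep(0, n / 2 - 1)))
  gm <- genotype_matrix(cbind(keepme = col_keep, dropme = col_drop),
                        sprintf("s%03d", 1:n), c("keepme", "dropme"))
  samples <- data.frame(sample_id = sprintf("s%03d", 1:n),
                        status = rep(0:1, n / 2), age = 60,
                        institution = "a", ethnicity = eth,
                        stringsAsFactors = FALSE)
  res <- qc_snps(gm, samples)
  expect_identical(res$genotypes$snp_ids, "keepme")
  expect_match(res$log$reason[res$log$id == "dropme"], "maf")
})

test_that("sample call-rate filter is strict at 0.90", {
  calls <- matrix(rbinom(300, 2, 0.4), 3, 100)
  calls[1, 1:11] <- NA   # call rate 0.89 -> removed
  calls[2, 1:10] <- NA   # call rate 0.90 exactly -> kept
  gm <- genotype_matrix(calls, c("low", "edge", "full"),
                        sprintf("m%03d", 1:100))
  res <- qc_samples(gm)
  expect_identical(res$log$id, "low")
  expect_setequal(res$genotypes$sample_ids, c("edge", "full"))
  expect_equal(nrow(qc_samples(res$genotypes)$log), 0)
})
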