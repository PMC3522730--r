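Package: snpsetkm
Title: SNP-Set Kernel-Machine Association Testing for Pathway Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical SNP-set association analysis for candidate-pathway
    case-control studies. Implements genotype and annotation input with
    call-rate, Hardy-Weinberg and minor-allele-frequency quality control,
    principal-component estimation of genetic ancestry from ancestry
    informative markers, the logistic kernel-machine variance-component score
    test with a linear kernel and Davies/Imhof characteristic-function
    p-values (Liu moment-matching fallback) at pathway, sub-pathway and gene
    level, per-SNP codominant and log-additive logistic models, permutation
    min-P family-wise error control, cohort descriptive tests, a
    detectable-odds-ratio power calculator, and a synthetic two-population
    case-control cohort generator with linkage disequilibrium and
    frequency-matched controls for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
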