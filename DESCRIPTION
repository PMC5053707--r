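Package: methcouple
Title: Phenotype-Specific Enhancer-Gene DNA Methylation Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers enhancer-gene DNA methylation couplings that separate
    colorectal-cancer phenotypes (CIMP versus non-CIMP). Implements windowed
    differentially-methylated-region (DMR) detection from bisulfite CpG counts
    with a binomial logistic-regression window test and FDR control, enhancer
    containment overlap against a validated enhancer catalog, differential
    enhancer selection by two-sample t-test, an intrachromosomal Pearson
    correlation screen between enhancers and distal DMRs, strand-aware gene
    annotation with promoter and TSS distance conventions, and an independent
    capture-seq validation stage based on region rpkm. A seeded synthetic-data
    generator plants ground-truth DMRs and latent-factor-coupled enhancer
    partner pairs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
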