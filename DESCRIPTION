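Package: stimgrid
Title: TCR/CD28 Stimulation-Grid Analysis of T-Cell Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies activation-induced genes in naive and memory CD4
    T cells as TCR- or CD28-sensitive from a seven-condition stimulation
    titration grid, using negative-binomial GLM likelihood-ratio tests
    under linear (dose) and switch (presence) models with linear-model
    prioritisation. Includes median-of-ratios normalization, dispersion
    estimation with trend shrinkage, Wald pairwise differential
    expression, preranked permutation gene-set enrichment, LD-based GWAS
    locus construction with a gene-matched permutation enrichment null,
    PWM motif scanning with allele-specific disruption scoring, and
    chromatin window-coverage analytics. A synthetic-data module generates
    count matrices, genotype panels with LD blocks, and peak sets with
    planted motifs so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    fgsea,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
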