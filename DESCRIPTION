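Package: toxqtl
Title: Quantitative Genetics of Topoisomerase II Poison Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantitative-genetics toolkit for mapping natural
    variation in drug response from high-throughput nematode phenotyping
    data. Implements well-level phenotype summarisation and normalisation
    (assay regression, IQR-based outlier pruning, control regression),
    broad-sense heritability estimation, correlation-LOD linkage mapping on
    recombinant inbred advanced intercross panels with permutation-based
    genome-wide thresholds and 1.5-LOD-drop intervals, kinship-corrected
    mixed-model association (exact EMMA-style REML), simulation-calibrated
    regions of interest, Spearman fine mapping of annotated variants,
    sliding-window Tajima's D, and allele-enrichment statistics for pooled
    CRISPR editing experiments. Ships simulators for every input (advanced
    intercross genotypes, structured wild panels, QTL-bearing phenotypes,
    sorter-style well records, pooled amplicon read counts) so the full
    pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-methods.R'
    'simulate.R'
    'phenotype.R'
    'linkage.R'
    'gwas.R'
    'finemap.R'
    'popgen.R'
    'crispr.R'
    'io.R'
    'pipeline.R'
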