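Package: metabotyper
Title: Genetic Architecture of the Plasma Metabolome: Regional Association,
    Conditional Analysis and Genetically Influenced Metabotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for untargeted metabolomics genome-wide
    association studies. Provides cohort simulation with linkage-disequilibrium
    structured genotypes and planted genetic effects, metabolite preprocessing
    (log transform, winsorization, covariate residualization), per-cohort
    association testing with inverse-variance weighted fixed-effect
    meta-analysis, LD-based genomic region definition, exact forward stepwise
    conditional analysis with variance-explained partitioning by minor allele
    frequency bin, partitioning of regional variant-metabolite associations
    into genetically influenced metabotypes (GIMs), candidate causal-gene
    annotation with fuzzy text matching and binomial enrichment against
    inborn-error-of-metabolism gene lists, metabolite genetic-score
    phenome-wide association with Mendelian-randomization follow-up, and
    Gaussian graphical model reconstruction of the metabolic network via
    multiple imputation and shrinkage partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
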