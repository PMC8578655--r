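Package: sqtlkit
Title: Splicing QTL Mapping, GWAS Meta-Analysis, Fine-Mapping and
    Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable genotype-to-splicing analysis pipeline: percent
    spliced in (PSI) and intron-retention quantification from splice
    junction read counts with quantifiability thresholds, splicing QTL
    (sQTL) association with rank-based inverse-normal transformation and
    covariate residualization, fixed-effects inverse-variance GWAS
    meta-analysis with sex-heterogeneity testing and genomic inflation,
    single-causal-variant fine-mapping via Wakefield approximate Bayes
    factors with credible sets, Bayesian colocalization of two
    association signals, and RT-PCR percent-intron-retention
    densitometry. A synthetic-data module generates genotypes with
    tunable minor allele frequency and local linkage disequilibrium,
    genotype-dependent junction counts for a cassette-exon plus
    retained-intron splicing event, covariates, quantitative phenotypes,
    and gel band intensities, so the full pipeline is testable without
    protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
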