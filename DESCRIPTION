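Package: dexnet
Title: Integrative Differential-Expression Meta-Analysis and Network Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for integrative transcriptomic and network
    analysis of case/control cohorts: random-effects meta-analysis of
    differential expression (Hedges' g, DerSimonian-Laird, permutation FDR),
    covariate adjustment (empirical-Bayes batch correction, surrogate
    estimation, robust residualization), Kolmogorov-Smirnov-like gene-set
    enrichment with gene-label permutation, drug-connectivity scoring from
    replicate compound signatures (prototype ranked lists, modified KS
    statistic, chemogenomic target-class enrichment), transcription-factor
    regulon and kinase-substrate enrichment over protein-interaction
    networks, seed-gene correlation signatures (Fisher z, Stouffer
    consensus), and Bayesian colocalization of GWAS and eQTL summary
    statistics. Includes synthetic-data generators with known ground truth
    for every input class, so the full pipeline is testable without any
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    sva
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
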