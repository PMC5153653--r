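Package: medipdmr
Title: Differential Methylation Regions from MeDIP Tiling Arrays with
    Multivariate Phenotype Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for binary methylation-enrichment calls from
    MeDIP (methylated-DNA immunoprecipitation) promoter tiling arrays in a
    cattle cloning cohort. Delineates regions of interest by an
    anchor-extension probe clustering strategy, identifies age-related and
    cloning-related differentially methylated regions by likelihood-ratio
    comparison of nested binomial models with Benjamini-Hochberg correction,
    and summarizes per-individual methylation as percentages of enriched
    probes. Integrates methylation with liver histopathology and fatty-acid
    phenotypes through multiple correspondence analysis of lesion scores
    (with rare-category merging), principal component analysis of
    rank-converted fatty-acid percentages, and multiple factor analysis over
    variable sets with an illustrative group variable. Group comparisons use
    exact or Monte-Carlo permutation tests, optionally stratified, and
    Spearman rank correlations. A seeded synthetic-data generator with
    planted differentially methylated regions supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
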