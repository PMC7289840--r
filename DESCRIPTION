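Package: oralung
Title: Oral-Taxa-Aware Diversity Analysis of Lung Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Diversity analysis of bronchoalveolar lavage fluid (BALF)
    16S communities with explicit handling of oral-cavity taxa. Implements
    inverse Simpson alpha-diversity, Morisita-Horn and between-taxa Jaccard
    dissimilarities, selection of oral "inhabitant" and "vagrant" taxa from
    Human Microbiome Project style prevalence tables using a Wilson-score
    prevalence criterion, a random-taxa-subset null distribution that scores
    the effect of selecting a taxa set as an ECDF percentile rank, permutation
    Mann-Whitney tests, bootstrap confidence intervals for diversity-on-BVAS
    regression slopes, single-predictor PERMANOVA on Gower-centered
    distances, dual hierarchical clustering (complete linkage on samples,
    single linkage on taxa), and a Dirichlet-multinomial cohort simulator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    biomformat,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
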