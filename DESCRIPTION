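Package: gpdscan
Title: Detecting Assortative Mating from Gametic Phase Disequilibrium
    Between Chromosome-Set Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the genomic signature of assortative mating as
    gametic phase disequilibrium (GPD): the residual correlation between
    polygenic scores built from disjoint chromosome sets (odd versus even
    numbered chromosomes), adjusted for chromosome-set principal
    components to control population stratification. Provides a forward
    in-time mating simulator with tunable spousal phenotype correlation,
    Mendelian transmission and discrete population structure; phenotype
    curation (rank-based inverse normal transformation and questionnaire
    encodings); variant quality control, per-variant association,
    effect-size shrinkage and chromosome-set score construction;
    leave-one-group-out and leave-one-region-out orchestration with
    inverse-variance fixed-effect meta-analysis; a single-outlier test
    for transchromosomal imbalance; and the closed-form expected GPD
    under equilibrium assortative mating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
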