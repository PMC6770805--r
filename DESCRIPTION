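Package: caprigen
Title: Pedigree-Based Genetic Evaluation of Dairy Goat Milk Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Repeated-records animal-model evaluation of dairy goat lactation
    traits (210-day milk, fat, protein and dry matter yields) with and without
    the alpha-S1 casein (CSN1S1) genotype as a fixed effect. Provides pedigree
    utilities (Meuwissen-Luo inbreeding, tabular relationship matrices,
    Henderson's sparse inverse of the numerator relationship matrix), EM/AI-REML
    variance-component estimation with permanent-environment effects, BLUP
    breeding values with standard errors of prediction, accuracies and
    reliabilities, a combined selection index with stratified sampling, a
    nonparametric pre-model screen (Kruskal-Wallis, Dunn, Shapiro-Francia,
    partial eta squared), and a synthetic-data generator that emulates the
    pedigree, genotype and lactation structure of a Murciano-Granadina
    breeding-program dataset so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    car,
    e1071,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
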