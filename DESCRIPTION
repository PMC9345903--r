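Package: slscreen
Title: Synthetic-Lethality Screening from Tumor Mutation and Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-procedure screen for candidate synthetic-lethal (SL)
    interactions between driver mutations and druggable genes in tumor
    cohorts: differential partner expression in driver-mutant tumors
    (Wilcoxon), pairwise co-expression in adjacent normal tissue (Spearman),
    Gene Ontology functional similarity (Wang semantic similarity, geometric
    mean of MF and CC gene similarities), and mutual exclusivity of somatic
    mutations against a margin-aware Poisson-binomial null. Screen survivors
    are ranked by Stuart order-statistics rank aggregation, joined to a
    drug-target catalog, and scored against cell-line-trained ridge models
    of drug response; an elastic-net transcriptome classifier of mutation
    status with leave-one-study-out validation and survival-based pair
    validation complete the pipeline. A synthetic-cohort generator with
    planted SL structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    glmnet,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
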