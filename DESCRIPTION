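Package: tfcombo
Title: Combinatorial Transcription-Factor Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the subset of transcription factors (TFs) whose
    aggregated (union) target set is most significantly over-represented
    among differentially expressed genes. Enrichment of a TF combination is
    scored by a one-sided Fisher exact test on the union of the member TFs'
    target sets, carried in log10 space end-to-end. The exponential space of
    TF combinations is explored with greedy heuristics, steepest-descent
    local search, and simulated annealing; significance of the best
    combination is calibrated against a profile-randomization null.
    Includes readers for RegulonDB-style TF-gene tables and plain edge
    lists, a gene-wise z-score differential-expression caller for
    expression matrices, a synthetic network and perturbation-trial
    simulator, and benchmark drivers comparing the combinatorial search
    with the standard per-TF enrichment test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
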