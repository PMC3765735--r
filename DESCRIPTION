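Package: culmnet
Title: Expression Profiling and Regulatory-Network Integration for
    Un-Replicated Tag-Count Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-omics expression studies of the
    six-library bamboo culm design (four developmental stages plus three
    internode positions, no replicates): exact conditional tag-count tests
    for differential expression with Benjamini-Hochberg control, short
    time-series model-profile clustering with permutation-expected counts
    and binomial significance, miRNA-target anti-correlation and
    mRNA-protein positive-correlation screens with Fisher's exact target
    enrichment, intersection of the screened pairs with significant
    temporal profiles, and assembly of the resulting typed regulatory
    network. Includes a synthetic-study generator with known ground truth
    so every stage can be exercised and validated without raw sequencing
    data.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
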