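Package: maturnet
Title: Mixed-Model Transcriptomics of Fetal Muscle Maturity in a Reciprocal Cross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for a two-age by four-genotype
    reciprocal-cross microarray design with litters as a random effect.
    Fits a per-probe linear mixed model (gestational age, fetal genotype,
    their interaction, and a random sow intercept) by profile maximum
    likelihood, tests it against the null model with a generalised
    least-squares F-type test, classifies differentially expressed probes
    into four fixed-effect sub-models by BIC, and tests age-by-maternal and
    age-by-paternal genotype interactions to separate the parental-genome
    contributions. Downstream stages include fold-change-filtered
    hypergeometric gene-set enrichment, a hard-thresholded Pearson
    relevance network with fast-greedy modularity communities and
    degree/betweenness hub ranking, and Pfaffl-method relative qPCR
    quantification with standard-curve efficiency estimation. A synthetic
    data generator reproduces the statistical structure of the design
    (18 sows, ~61 fetuses, 8 conditions, planted effect classes and
    correlated gene blocks) so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
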