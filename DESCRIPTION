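Package: vapelens
Title: Infodemiology Pipeline Linking E-Liquid Flavor Mentions to Health-Symptom Mentions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how e-cigarette users discuss
    e-liquid flavors and health symptoms on social media. Provides keyword
    taxonomies with sentence-level disambiguation, Apriori frequent-itemset
    mining for lexicon enrichment, monthly trend normalization, lexicon-based
    sentiment scoring with health-keyword neutralization and two-proportion
    tests, latent Dirichlet allocation by collapsed Gibbs sampling with
    collocation merging, and binomial-logit generalized estimating equations
    with exchangeable working correlation and Tukey-adjusted pairwise flavor
    contrasts. A seeded synthetic-corpus generator with user-level clustering
    makes every stage testable without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
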