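Package: gutsig
Title: Microbiome-Based Subtyping of Autistic Children from Genus-Level
    Gut Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for discovering a compact genus-level
    gut-microbiome signature associated with behavioral severity in autism
    spectrum disorder, subtyping children into two microbiome-defined
    subpopulations by average-linkage clustering on Bray-Curtis
    dissimilarity, and classifying new samples with a k-nearest-neighbors
    model evaluated by leave-one-out cross-validation. Includes CARS
    behavioral domain scoring, alpha diversity (observed features, Shannon,
    Pielou, Faith phylogenetic diversity), principal coordinates analysis,
    permutation-based Kruskal-Wallis and Spearman inference, 2x2
    contingency statistics, Benjamini-Hochberg correction, and a seeded
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
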