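Package: drugrepo
Title: Multi-Layer Drug Similarity Integration for ATC-Based Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the therapeutic class (ATC level 2) of drugs from three
    integrated dissimilarity layers: chemical structure (Jaccard, cosine and
    Dice similarities on binary fingerprints), molecular targets (set overlap
    combined with shortest-path distances on a protein-protein interaction
    network), and drug-induced gene expression (a weighted Spearman's Footrule
    on signed p-value rank profiles). The fused dissimilarity matrix is
    embedded by classical multidimensional scaling, the embedding dimension is
    chosen by cross-validated error of a Gaussian-kernel multiclass support
    vector machine, and repeated 90/10 subsampling turns systematic
    misclassifications into scored drug repositioning candidates. Includes a
    synthetic cohort generator with planted class structure and controllable
    mislabelling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
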