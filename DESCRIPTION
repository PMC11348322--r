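Package: codroplet
Title: Co-Condensation Propensity Prediction for Protein Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the propensity of two proteins to partition into the
    same biomolecular condensate.  A pair-representation transformer with
    gated, pair-biased self-attention consumes AlphaFold2-style residue
    features (single, pair and structure representations), combines the
    two chains into one residue graph and predicts a co-condensation
    probability for the pair.  The package also builds labelled pair
    datasets from condensate membership tables (within-condensate
    positives, non-co-occurring negatives, self-pair expansion with
    interaction-network exclusion, sequence-identity and length filters,
    condensate-aware train/test splitting), trains and evaluates the
    network (cross-entropy with L2, minibatch gradient descent,
    ROC/AUC/MCC reporting), provides a deterministic surrogate feature
    generator with planted pairwise-compatibility structure for
    desk-scale experiments, and implements downstream condensate
    analyses: membraneless-organelle versus random score comparisons,
    scaffold-client scoring, proteome-wide pair enumeration, partner
    counting and amino-acid composition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
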