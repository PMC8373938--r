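Package: confold
Title: Contact-Guided Coarse-Grained Protein Folding by Replica-Exchange
    Fragment Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale engine for contact-guided ab initio protein
    structure assembly. Predicted residue-residue contact maps from
    multiple predictors are combined by reliability tier, filtered by
    MSA-depth-dependent confidence cutoffs, and converted into a smooth
    three-gradient restraint potential that is embedded in a
    coarse-grained (C-alpha plus virtual C-beta) force field together
    with fragment-derived distance profiles. Conformations are sampled
    by replica-exchange Monte Carlo fragment assembly, decoys are
    clustered to select final models, and models are scored by
    TM-score, C-alpha RMSD, contact precision and restraint
    satisfaction. A fixtures module generates reproducible synthetic
    folds, calibrated noisy contact ensembles, synthetic alignments and
    a miniature fragment source library for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
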