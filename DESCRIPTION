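Package: mhc2align
Title: Pan-Specific MHC Class II Binding Prediction with Concurrent Core
    Alignment
Version: 0.1.0
Authors@R:
    person("mhc2align", "developers", email = "mhc2align@example.org",
           role = c("aut", "cre"))
Description: Trains and applies pan-specific feed-forward neural networks
    for peptide binding to MHC class II molecules.  The training procedure
    concurrently identifies the 9-mer binding core of each peptide and
    updates the network weights by online backpropagation, taking the
    peptide core, flanking-region summaries, length features and the MHC
    pseudo sequence as input.  Includes cross-validated ensembles with
    majority-vote core assignment, leave-one-allele-out and leave-one-
    peptide-out benchmark protocols, a source-protein overlapping-window
    ligand benchmark, BLOSUM50 pseudo-sequence allele distances, AUC and
    Pearson-correlation evaluation, and a synthetic data generator with
    planted binding motifs for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
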