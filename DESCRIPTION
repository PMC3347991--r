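Package: pinemir
Title: Homology-Based miRNA Discovery and Characterization from Plant Transcriptomes
Version: 0.1.0
Authors@R: person("Maintainer", "Pinemir", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies conserved microRNAs in assembled plant transcriptomes
    by homology to known mature miRNAs, folds candidate precursor windows with
    a nearest-neighbor minimum-free-energy model, classifies hairpins by
    MFE/MFEI/A+U-content/duplex-mismatch criteria, assigns miRNA families and
    summarizes the resulting catalog, predicts miRNA targets with a
    penalizing-score complementarity scheme including cleavage-site mapping,
    and quantifies relative miRNA expression from qPCR Ct tables with the
    comparative-Ct (2^-ddCt) method. Includes a synthetic-data generator that
    plants ground-truth precursors, decoys and target sites so the whole
    pipeline is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
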