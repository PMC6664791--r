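Package: irescan
Title: Length-Independent Sequence and Structure Features for IRES Prediction
Version: 0.1.0
Authors@R:
    person("irescan", "developers", email = "irescan@example.org", role = c("aut", "cre"))
Description: Computes length-independent features of RNA segments for
    internal ribosome entry site (IRES) prediction: global and windowed
    local kmer frequencies, sequence-structure triplet features derived
    from predicted secondary structure, and the Q_MFE permutation
    statistic based on dinucleotide-preserving Euler shuffles. Includes
    a gradient-boosted tree classifier with the published hyperparameter
    surface, dataset construction from bicistronic-assay activity
    tables, a synthetic fixture generator, sliding-window scanning of
    long sequences with BED export, and a command-line interface.
License: MIT + file LICENSE
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
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
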