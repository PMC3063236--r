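Package: cdr3stalk
Title: Structural Analysis of the Glycine/Serine Variation in the TCR CDR3beta Stalk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of the buried glycine/serine
    variation at IMGT position 107 of the T-cell receptor CDR3beta stalk.
    Parses protein structures in PDB format, anchors IMGT positions onto
    author numbering from the CDR3beta sequence, measures the stalk
    distance triple (opposing-strand carbonyl carbon, Y40 hydroxyl,
    residue-42 alpha carbon) with group summaries, models a G107S
    substitution on a fixed backbone by discrete chi1 rotamer placement
    scored by steric clashes, cavity probing and hydrogen bonding, and
    estimates quasi-harmonic (covariance-matrix) conformational entropy of
    trajectory ensembles.  Includes deterministic generators for idealized
    beta-hairpin fixtures, Gaussian-fluctuation trajectories with
    closed-form entropy, and toy TRBV sequence sets for the C-terminal
    motif census.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
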