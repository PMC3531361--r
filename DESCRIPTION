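Package: coevoscan
Title: Intramolecular Covariation, CAPS-Style Coevolution and Mirrortree
    Analysis of Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects coevolving residues in protein multiple sequence
    alignments and correlated evolution between protein families.
    Implements physicochemical covariation between alignment columns with
    Vingron-Argos sequence weighting and effective-sample-size significance
    tests, CAPS-style correlated evolutionary-rate detection with
    divergence-time-normalised substitution scores, resampling significance
    and compensatory-mutation (hydrophobicity/molecular-weight)
    correlations, and mirrortree correlation of Poisson-corrected
    evolutionary distance matrices between ligand and receptor domains.
    Ships a synthetic-data generator that evolves protein families along a
    shared phylogeny with planted compensatory site pairs and tunable
    inter-family rate sharing, so every statistic is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
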