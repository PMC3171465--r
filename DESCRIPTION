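Package: sdpscan
Title: Detection of Specificity-Determining Positions in Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heuristic detection of functional divergence in families of
    paralogous proteins, one alignment column at a time. Scores within-group
    residue conservation (entropy, exchangeability-corrected entropy,
    Jensen-Shannon divergence from the stationary distribution) and
    across-group distribution overlap (normalized overlap, squared difference,
    expectation-corrected overlap, mutual information), and combines them
    under a determinant or discriminant model of evolution into a single
    per-position specialization score. A continuous-time Markov model of
    amino-acid replacement (any PAML-dialect rate matrix; WAG bundled)
    supplies the free-evolution expectations and a family-wide effective
    divergence time. Includes ROC-based evaluation against residue-level
    annotation, a planted-signal alignment simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
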