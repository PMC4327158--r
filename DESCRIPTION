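Package: absubst
Title: Antibody-Specific Amino Acid Substitution Models from Repertoire
    Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates empirical amino acid substitution models tailored to
    antibody somatic hypermutation from repertoires of immunoglobulin
    variable-region sequences.  Sequences are sorted into gapless
    ("homogeneous") multiple sequence alignments sharing identical
    framework and CDR fragment lengths, genealogies are inferred per
    alignment, and a reversible 20-state exchangeability model is learned
    by expectation-maximization under a gamma-plus-invariant-sites rate
    model.  Includes column-bootstrap confidence analysis of the estimated
    exchangeabilities, network-modularity interpretation of substitution
    patterns, model comparison by per-site log-likelihood with Wilcoxon
    signed-rank testing, and a synthetic-repertoire simulator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
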