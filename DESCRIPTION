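Package: pwmsa
Title: Multiple Alignment of Highly Diverged Protein Sequences via
    Position-Weight-Matrix Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multiple sequence alignments for highly diverged protein
    families by optimizing a position weight matrix (PWM) "image" of the
    alignment with a genetic algorithm, aligning every sequence to the PWM by
    global affine-gap dynamic programming, and assembling the induced multiple
    alignment. Statistical significance of any alignment is assessed by a
    Monte Carlo Z-score over residue-shuffled null sets. Includes a calibrated
    protein-family simulator (ancestor plus independently mutated descendants
    with a closed-form substitutions-per-residue divergence model) and a
    reference-based column score for alignment quality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
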