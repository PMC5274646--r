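Package: seedaln
Title: Adaptive-Seed Protein Similarity Search and Homology Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast yet sensitive protein similarity search by suffix-array
    adaptive seeding: seeds are chosen per query position as the shortest
    exact match occurring no more than m times in the library, then widened
    by gapless and gapped X-drop extension under an arbitrary substitution
    matrix with affine gap costs. E-values for any scoring scheme are
    obtained from Karlin-Altschul theory (analytic ungapped lambda) and
    Monte-Carlo Gumbel calibration for gapped scores. Includes a rigorous
    Smith-Waterman baseline, SCOP-style superfamily/fold benchmark
    evaluation (weighted ROC with FDR cut-off, ROC_n scores, alignment
    sensitivity/precision curves), and a synthetic remote-homology
    benchmark generator with exact ground-truth alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
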