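Package: kssdr
Title: Genome Distance Estimation by K-mer Substring Space Decomposition Sketching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sketch-based estimation of genome distances. Genomes are reduced
    to sketches by decomposing the space of all length-s k-mer center
    substrings with a seeded random permutation and keeping the k-mers whose
    center substring falls in one selected subspace. Kept k-mers are encoded
    with an invertible (one-to-one) hash, so sketches support exact set
    algebra (union, intersection, subtraction for variant enrichment).
    All-vs-all Jaccard and containment based distances (Mash distance and
    alignment-and-assembly-free distance) are computed through a unified
    inverted-index dictionary with sharded, indexed output. Includes a
    synthetic-genome generator with a known substitution rate for validating
    distance recovery, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
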