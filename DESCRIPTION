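Package: divrep
Title: Detection of Highly Divergent Tandem Repeats in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tandem repeats in amino-acid sequences that have diverged
    far beyond the reach of similarity-based repeat finders. Sequences are
    re-coded into five physicochemical groups and locally aligned against a
    cyclic periodic probe under pair-correlation position-weight matrices that
    are refined iteratively; significance is assessed by Monte-Carlo shuffling
    (Z-score), calls are post-processed into non-redundant annotations with a
    divergence degree S, and repeat weight matrices can be clustered by cyclic
    Euclidean distance. Includes the artificial tandem-repeat benchmark
    generator and its evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
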