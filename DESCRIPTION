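Package: nestedmir
Title: Nested miRNA Precursor Detection, Conservation and Promoter Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of nested microRNA genes on
    fold-back precursors. Reads miRBase-dialect hairpin and mature FASTA,
    predicts or ingests stem-loop secondary structure, locates miRNA/miRNA*
    duplexes, decides nestedness and assigns sibling names (x.k-5 / x.k-3),
    profiles cross-species conservation of aligned stem-loops, reconstructs
    neighbor-joining phylogenies from p-distances or Jukes-Cantor distances,
    performs exact transcription-start-site-relative promoter truncation and
    deletion bookkeeping with IUPAC cis-element scanning, and computes
    2^-deltaCt relative expression from qPCR Ct tables. Every input class has
    a seeded synthetic generator with known ground truth, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
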