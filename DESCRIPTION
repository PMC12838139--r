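Package: diagprimer
Title: Species-Diagnostic PCR Primer Design from Protein-Coding Marker Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and validate species-specific PCR assays from a set of
    protein-coding marker sequences (for example mitochondrial COI barcodes).
    The toolkit aligns coding sequences codon-aware, characterizes
    interspecific divergence (base composition overall and by codon position,
    uncorrected p-distances with pairwise deletion, hypervariable windows),
    enumerates primer candidates whose 3'-terminal bases fall on
    species-diagnostic sites, scores them with a nearest-neighbor melting
    temperature model and structure heuristics, pairs and ranks them, and
    verifies specificity by mismatch-tolerant in-silico PCR against single
    templates and mixed-template mock communities. A seeded synthetic
    marker-family generator with planted diagnostic sites makes the whole
    pipeline testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
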