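Package: acsarch
Title: Motif-Architecture Classification of ACC Synthase-Like Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether an ACS-like protein is a genuine
    1-aminocyclopropane-1-carboxylate synthase (ACS) from its sequence:
    ungapped protein motif discovery (ZOOPS expectation-maximisation) and
    scanning with exact position p-values, assessment of the ordered
    nine-motif ACS architecture, mapping of the key catalytic residues
    (the cross-subunit glutamine in motif 2 and the PLP-contacting
    asparagine) onto a reference by global alignment, a conjunctive
    classifier over motifs and key residues, neighbor-joining phylogenies
    with bootstrap support and monophyly tests, crystal-structure
    superposition with active-site comparison, and a synthetic
    protein-family generator with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
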