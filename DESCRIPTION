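Package: epcAncestry
Title: Bacterial and Archaeal Ancestry of Eukaryotic Gene Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale pipeline for quantifying the bacterial versus archaeal
    ancestry of eukaryotic gene repertoires. Clusters proteomes into protein
    families by reciprocal best hits (exact affine-gap Smith-Waterman with
    Karlin-Altschul E-values) and Markov clustering, merges eukaryotic families
    with prokaryotic families into eukaryote-prokaryote clusters (EPCs) by the
    reciprocal best cluster rule, rechecks exclusivity against the other
    prokaryotic domain, and estimates per-genome bacterial/archaeal gene
    proportions with a genus-stratified downsampling estimator that corrects
    for taxon-sampling imbalance between bacteria and archaea. Includes a
    seeded synthetic proteome generator with planted family structure for
    validation, majority-rule functional annotation, and presence/absence
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    graphics,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
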