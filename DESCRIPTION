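Package: codimr
Title: Drug-Induced Transcriptional Modules and Their Conservation Across
    Cell Types and Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and characterization of drug-induced transcriptional
    modules from drug-treatment expression compendia. Implements the
    Iterative Signature Algorithm (ISA) for biclustering genes with the drug
    treatments that coherently regulate them, post-hoc filters that remove
    constitutive coexpression modules, small modules and redundant modules,
    cross-dataset module matching by hypergeometric gene overlap with
    reciprocal best hits to build conserved drug-induced modules (CODIMs), a
    permutation test for cross-species module conservation, a functional
    coherence test against gene-gene association networks, drug-set
    enrichment over annotation catalogs (targets, ATC classes, side effects,
    chemical fragments) with Tanimoto-based selection of repositioning
    candidates, and two-parameter log-logistic dose-response fitting with
    Cheng-Prusoff conversion of IC50 to Ki. A synthetic-data generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
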