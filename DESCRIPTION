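Package: uvaregnet
Title: Multi-Omics Inference of UV-A-Responsive Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for going from gene expression and
    metabolite abundance matrices plus promoter sequences to differentially
    expressed genes and accumulated metabolites, coexpression modules, and
    transcription-factor to structural-gene regulatory networks, as used in
    time-course UV-A supplementation experiments on leafy crops. Implements
    median-of-ratios normalization with Welch tests and Benjamini-Hochberg
    adjustment, OPLS-DA with VIP scores for metabolite selection, soft-threshold
    coexpression module detection with topological overlap and module
    eigengenes, position weight matrix promoter scanning with exact p-values
    from a dynamic-programming score distribution, motif-plus-correlation
    regulatory network assembly, hypergeometric gene-set enrichment, and
    neighbor-joining phylogenies with bootstrap support. A synthetic-data
    generator with planted ground truth makes every stage verifiable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
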