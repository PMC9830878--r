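Package: xylocomp
Title: Cross-Species Single-Cell Comparison of Wood-Forming Xylem Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing single-cell transcriptomes of
    stem-differentiating xylem within and across tree species: quality
    filtering and IO for 10x-style sparse count matrices and OrthoMCL-style
    ortholog groups, per-cell normalization and a negative-binomial exact
    test with dispersion shrinkage (sSeq-style, with an asymptotic beta
    switch for large counts), anchoring of single-cell clusters to laser
    capture microdissection (LCM) bulk cell types, ortholog-group count
    aggregation with best-hit and mutual-best-hit cross-species cluster
    matching, a minimum-spanning-tree distribution-overlap statistic on
    labeled 2D embeddings, Gaussian-kernel gene-set smoothing and
    Nadaraya-Watson pseudotime profiles, and a two-species synthetic data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    vegan,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
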