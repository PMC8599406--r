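Package: evodet
Title: Determinants of Sequence-Evolution Constraint from Gene-Level Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models which gene-level variables determine constraint on protein
    sequence evolution, as measured by dN or a per-gene conservation score such
    as phyloP. Provides feature-table preprocessing (one-hot encoding,
    amino-acid proportion scaling, centring/scaling, iterative k-NN
    imputation), protein-protein interaction network centralities from
    STRING-format edge lists, single-response partial least squares and
    principal-components regression with cross-validated component selection,
    variable importance in projection (VIP) scores, a per-variable variance
    decomposition for PCR, grouped Spearman partial correlations with
    Bonferroni adjustment, a random-forest baseline, and a synthetic-study
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
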