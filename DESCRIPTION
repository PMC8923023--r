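Package: dictynet
Title: Co-Expression Interactome Analysis of GTPase Regulatory Networks in Dictyostelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer putative interaction networks among small GTPases
    and their regulators (GEFs, GAPs) from multi-species developmental and
    cell-type specific transcript profiles. Raw read counts are standardized
    to fraction-of-maximum (or fraction-of-sum for two-part cell fractions),
    assembled into concatenated per-ortholog-family profile arrays across
    chosen species subsets, and clustered by agglomerative hierarchical
    clustering with Pearson-correlation distance. Trees are cut at a relative
    branch height, clusterings are scored by recovery of experimentally known
    primary and secondary interactions, clades receive multiscale-bootstrap
    approximately-unbiased (AU) support, and dendrograms built from different
    data subsets are compared by shared clades, Fowlkes-Mallows and cophenetic
    statistics. A synthetic-data generator with planted co-expressed modules
    supports calibration and testing, and per-family conservation and
    expression-class summaries are tabulated across five dictyostelid species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    readxl,
    withr
Config/testthat/edition: 3
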