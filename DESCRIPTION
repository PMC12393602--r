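Package: rarecnv
Title: Stratified Rare Copy-Number Variant Burden and Association Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case/control meta-analysis of rare copy-number
    variants (CNVs) called from heterogeneous SNP-array cohorts: per-sample
    intensity and call-count quality control, qualifying and analysis-grade
    call filters, ancestry clustering and array-group x ancestry x sex
    stratification, global CNV burden tests (logistic regression and
    stratified Cochran-Mantel-Haenszel carrier tests over size, genic and
    pLI-constraint classes), gene- and sliding-window carrier association
    with min(P) permutation genome-wide significance thresholds and
    family-wise error rate adjusted p-values, merging of stratified count
    tables from external cohorts, and a synthetic stratified cohort
    generator with planted risk loci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
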