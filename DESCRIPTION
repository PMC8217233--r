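Package: proteoformr
Title: Correlation-Based Detection of Functional Proteoform Groups in
    Bottom-Up Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects functional proteoform groups from peptide-level
    bottom-up proteomics quantification matrices by peptide correlation
    analysis. Sibling peptides of a protein are clustered on correlation
    distance by average-linkage hierarchical clustering, a proteoform score
    (within-cluster minus across-cluster mean Pearson correlation) is tested
    with a Fisher z-transformation statistic, and p-values are corrected by
    the Benjamini-Hochberg procedure. Includes the preprocessing chain for
    size-exclusion co-fractionation (SEC-SWATH-MS) and sample-wise datasets,
    a sequence-proximity permutation test for the biological credibility of
    detected groups, an in silico spike-in benchmark with ROC and empirical
    FDR evaluation, and proteoform-group quantification with two-way ANOVA
    testing of condition specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
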