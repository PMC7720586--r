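Package: ctcmut
Title: Somatic Mutation Concordance Between Matched Primary Tumors and
    Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("ctcmut", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Compares somatic mutation profiles between matched lesion pairs
    (a primary tumor and a circulating-tumor-cell sample per case): regional
    classification of mutations into common and lesion-specific categories,
    concordance and abundance statistics, functional-consequence tables and
    NS/S ratios, 6- and 96-class trinucleotide mutation spectra, mutational
    signature refitting by non-negative least squares against a supplied
    catalog, hierarchical clustering of exposures, variant-allele-frequency
    clonality comparisons, and recurrence tabulation of cancer-gene
    mutations. Includes a trunk-branch clonal simulator that generates
    matched callsets with signature-specific contexts, beta-distributed
    allele frequencies and depth-dependent detection dropout, together with
    closed-form expectations used as oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    ape,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
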