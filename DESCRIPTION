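Package: popgenscan
Title: Sliding-Window Selection Scans and Structure Summaries for
    Multi-Population SNP Panels
Version: 0.1.0
Authors@R:
    person("popgenscan", "developers", email = "popgenscan@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic selection scans starting from a
    multi-sample VCF: hard-filter and site-level SNP filtering, sliding-window
    nucleotide diversity (Pi), weighted Weir-Cockerham FST and Tajima's D,
    joint FST-quantile plus reduced-Pi outlier-window detection with region
    merging, region-versus-background enrichment statistics (fold enrichment,
    percentile rank, exceedance fractions, Wilcoxon rank tests, Pi ratio and
    reduction-of-diversity), and basic structure summaries (p-distances,
    neighbor-joining trees, genotype PCA, a DAPC-style clustering procedure).
    Ships a Balding-Nichols island-model genotype simulator with known truth
    so every pipeline stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
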