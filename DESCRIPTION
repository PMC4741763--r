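Package: methsig
Title: Cross-Tissue Invasiveness Methylation Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNA methylation signatures shared by invasive cancer
    cell lines from different tissues of origin. Provides per-pair differential
    methylation calling on Illumina 450K-style beta-value matrices (moderated
    or Welch t on M-values, delta-beta and DiffScore conventions), three-way
    concordant intersection of hyper- and hypomethylated CpG sets, promoter and
    enhancer enrichment with exact log-space tail probabilities, integration
    with expression data (quantile normalization, fold-change/DiffScore calling,
    hypergeometric gene-list overlap), hierarchical clustering of samples, and
    a synthetic-data generator with planted ground truth so every stage of the
    pipeline is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
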