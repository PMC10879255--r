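Package: methgroups
Title: Consensus Methylation Group Discovery for Tumor WGBS Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised discovery of DNA methylation groups from whole-genome
    bisulfite sequencing (WGBS) cohorts, with the downstream characterization
    stages used in tumor methylome studies. Implements consensus k-means
    clustering with CDF/delta-area stability diagnostics, the gap statistic
    with a Monte-Carlo uniform reference, Ward hierarchical clustering and
    low-dimensional embedding; hypomethylated-region (HMR) segmentation with
    CpG island/shore/shelf and genomic-element annotation; coverage-based
    copy-number segmentation; TPM normalization with one-vs-rest differential
    expression and hypergeometric gene-set enrichment; and cohort-level group
    comparisons. A synthetic cohort generator plants known group structure
    (methylation blocks, CNV segments, differentially expressed genes,
    clinical covariates) so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    uwot,
    Rtsne,
    mclust,
    cluster,
    IRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
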