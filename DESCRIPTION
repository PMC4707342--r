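Package: myomics
Title: Multi-Omics Profiling of Uterine Leiomyosarcoma and Leiomyoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to distinguish uterine leiomyosarcoma (LMS) from benign
    leiomyoma (LM) and normal myometrium (NM) from array-based omics
    profiles: SNP-array LRR/BAF segmentation with copy-neutral LOH
    detection and a per-sample chromosomal-abnormality burden ratio;
    quantile normalization, one-way ANOVA with Benjamini-Hochberg
    correction and flag/intensity filters for tissue-specific expression
    markers; 450K-style beta-value differential methylation with
    gene-feature and CpG-island tabulation, region binning and two-sided
    marker selection; and COBRA methylation-index quantification with
    standard-curve correction.  A synthetic multi-omics generator plants
    known aberrations, expression effects, methylation differences and
    band intensities so that every stage can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
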