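Package: lenbias
Title: Diagnosis and Correction of Sample-Specific Gene-Length Bias in RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect, quantify and remove sample-specific gene-length
    bias in bulk RNA-seq count data. Provides diagnostics that measure the
    coupling between gene length and fold change across replicate samples,
    six classical between-sample normalization schemes (RPKM, RPKM followed
    by quantile normalization, TMM, RLE, RLE followed by RPKM, and upper
    quartile followed by RPKM), a covariate-aware corrector that removes
    per-sample length and GC-content effects by robust spline regression,
    pre-ranked gene-set enrichment analysis and a correlation-adjusted
    (variance inflation factor) gene-set test, a negative-binomial synthetic
    data generator with injected per-sample length-bias curves and
    co-regulated gene blocks, and a Monte-Carlo simulation quantifying how
    intergene correlation confined to extreme-length genes produces
    transcriptome-wide significant length-fold-change correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    optparse
Config/testthat/edition: 3
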