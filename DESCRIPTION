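Package: wifa
Title: Wavelet-Based Identification of Focal Genomic Aberrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects focal and broad DNA copy-number aberrations from
    multi-sample probe-level log2-ratio data (SNP arrays, array CGH).
    Per-sample signals are decomposed with a translation-invariant Haar
    stationary wavelet transform into a smooth low-frequency profile and a
    hard-thresholded high-frequency profile; high-frequency profiles are
    post-processed, summed across samples, clustered along the chromosome
    and assigned significance by a segment-permutation null, while summed
    low-frequency profiles are tested arm-wise against a
    histogram-convolution null with Storey q-value correction. Includes a
    synthetic multi-sample benchmark generator and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
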