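Package: peakproof
Title: Validation and Quality Control of ATAC-Seq Peak Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Validates ATAC-seq peak calls against histone-mark ChIP-seq
    truth sets and computes library quality-control metrics. Builds
    real-positive (H3K4me1/H3K4me3 peaks overlapping H3K27ac) and
    real-negative (H3K27me3) reference sets, computes base-level
    precision, recall and false-positive-rate curves over peak score
    cutoffs, selects filtering thresholds at the precision-recall
    intercept, and quantifies enrichment and replicate concordance
    (FRiP, Jaccard index, fingerprint curves, synthetic Jensen-Shannon
    distance, binned RPKM coverage, correlation and PCA). Relates
    promoter accessibility to gene expression, and ships a synthetic
    chromatin-accessibility data generator with known ground truth for
    closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
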