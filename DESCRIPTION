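Package: segfuse
Title: Fusion-Gene Detection from SNP-Array Copy-Number Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate fusion genes at unbalanced copy-number
    breakpoints using SNP-array segmentation profiles and probe-level
    intensities. Segmentation profiles are cleaned of single-probe
    artifacts, breakpoints are enumerated, nearby genes are anchored with
    5'/3' roles, and gene pairs are screened by copy-number agreement,
    strand orientation, fusion length and the concordance of loess-smoothed
    probe intensities across the putative junction (AICc-selected span,
    Pearson correlation, root-mean-square difference). Recurrent candidates
    are grouped across samples, tested for positional conservation and
    partitioned into subgroups by complete-linkage clustering. A synthetic
    cohort simulator with planted fusions, single-probe artifacts and
    copy-number-dependent intensity noise makes the full pipeline testable
    without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rtracklayer,
    GenomicRanges,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
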