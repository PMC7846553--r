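Package: coexdiff
Title: Differential Co-Expression Network Analysis of Two-Group Transcriptomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-by-gene and gene-to-gene analysis of two-group expression
    matrices. Implements three per-probe differential criteria (mean
    expression, area under the empirical cumulative distribution function,
    and bootstrap Shannon entropy on a common discretization grid) with
    Benjamini-Hochberg false discovery rate control; power and critical-value
    calibration for the underlying tests (Welch t, Wilcoxon by simulation,
    Fisher r-to-z critical correlations, Shapiro normality screening);
    correlation-bin co-expression networks with graph-theory summaries and
    node-subsampling inference; differential-correlation (Fisher r-to-z)
    edge networks and correlation-difference density summaries; a
    differential multiple-regression screen for group-specific four-probe
    linear relations; and a synthetic two-group data generator with planted
    effects and ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
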