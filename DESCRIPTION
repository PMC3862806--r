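Package: samde
Title: Moderated d-Statistic Differential Expression with Permutation FDR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for SAM-style differential expression analysis
    of log2 expression matrices: moderated d-statistics with data-driven s0
    selection, permutation-based false discovery rate estimation with
    symmetric delta cutoffs, empirical low-intensity filtering of bimodal
    intensity distributions, correlation-distance ordination and outlier-array
    QC, cross-dataset d-statistic concordance, gene-set distribution-shift
    testing, and Bonferroni-corrected over-representation analysis. Includes a
    synthetic-cohort generator with planted differential expression and
    ground-truth tables for calibration and recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
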