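Package: osmi
Title: One-Sample Imputation of Missing DNA-Methylation Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing DNA-methylation beta-values from a single
    methylome by nearest-CpG search along each chromosome strand (OSMI), with
    a CpG-island-aware variant that prioritises neighbours inside the same
    island. Includes parsers for Illumina 450K-style CpG annotation and UCSC
    cpgIslandExt island tracks, a greedy complete-case submatrix filter for
    matrices with missing entries, an MCAR masking and scoring harness
    (RMSE, MAE, residual summaries, paired signed-rank comparison with
    rank-biserial and Cohen's d effect sizes), and a synthetic methylome
    generator with clustered CpG positions and distance-decaying
    co-methylation for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
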