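Package: ogdrscreen
Title: Temporal Transcriptome Screening for Ischemia/Reperfusion Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A replicate-free RNA-seq screening pipeline for
    oxygen-glucose deprivation/reperfusion (OGD/R) style time courses:
    RPKM quantification, exact Poisson-ratio differential expression
    between single libraries with Benjamini-Hochberg FDR control,
    hypergeometric gene-set over-representation with Bonferroni and FDR
    adjustment, Pearson co-expression network construction with degree
    and k-core analysis, and a three-criteria key-gene screen. Includes
    a negative-binomial count simulator with planted differential
    expression, co-expressed modules, and enriched gene sets so the
    whole pipeline is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
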