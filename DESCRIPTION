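Package: miRTargetRank
Title: Chi-Square-Weighted Ranking of miRNA Target Genes from Lifespan Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Turns the results of a conditional miRNA overexpression lifespan
    screen into ranked lists of candidate target genes. Survival comparisons
    per transgenic line (Kaplan-Meier curves, Mantel-Cox log-rank chi-square,
    direction of the lifespan effect) are converted into signed per-miRNA
    average strengths, combined with miRNA-to-target prediction scores from
    four databases (MicroCosm, PicTar, microRNA.org, TargetScan), normalised
    and pooled across databases into a single gene ranking, and finally
    scored against an RNAi validation screen to quantify each database's
    predicting power. A synthetic-screen generator with planted essential
    genes makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
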