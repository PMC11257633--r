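Package: pairdose
Title: Dosage Sensitivity and Expression Buffering of X-Y Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for studying dosage sensitivity and
    post-transcriptional buffering of homologous X-Y gene pairs such as
    DDX3X/DDX3Y. Implements phylogenetic survival metrics (branch-length
    sums over species presence patterns and survival fractions), constraint
    percentile composites and expression-breadth scores, linear dose-response
    modelling of expression against sex-chromosome copy number in aneuploid
    cell panels, allelic-ratio (Xi/Xa) buffering tests, knockdown
    compensation indices, delta-delta-Ct fold changes, and mRNA half-life
    estimation from metabolic-labeling timecourses via saturation kinetics
    with bootstrap uncertainty. A synthetic-data module generates every
    input class with the statistical structure the analyses assume, so the
    full pipeline is testable without controlled-access sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
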