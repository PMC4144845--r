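Package: compscape
Title: Quantifying Compensatory Evolution in Gene-Deletion Laboratory Evolution
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laboratory evolution experiments that ask
    whether, and how, populations carrying deleterious gene deletions recover
    fitness.  Estimates relative fitness from plate-reader optical-density
    time series, calls compensated lines against an evolving wild-type
    control null, and quantifies the signatures of compensation: excess of
    nonsynonymous coding mutations (Poisson-binomial tail test), functional
    relatedness of de novo mutations to the deleted gene (permutation test),
    restoration of wild-type expression, conditional pleiotropy across
    environments, and suppression interactions in genetic-interaction maps.
    A synthetic-data module generates every input shape with known ground
    truth so the whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
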