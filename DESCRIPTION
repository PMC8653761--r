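Package: songvar
Title: Variance Partitioning of Birdsong Traits Across Social Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying listener-specific variation in birdsong.
    Computes recording-level song traits (length, tempo, short-term
    complexity, frequency statistics, k-means repertoire size, song rate)
    from syllable-level measurements, fits Gaussian linear mixed models by
    maximum likelihood with multiple random-intercept factors via a
    profiled deviance, partitions phenotypic variance into
    stimulus-identity, focal-male, year and residual components with
    parametric-bootstrap confidence intervals, and reports signed Cramer's
    V effect sizes from likelihood-ratio tests. Includes a synthetic
    song-corpus generator with known ground truth for validating the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    signal
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
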