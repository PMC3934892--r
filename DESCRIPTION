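Package: chartmetrics
Title: Perceptually Grounded Metrics for Color-Naming Response Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing distributions of color-naming responses
    ("charts") over a Munsell-style stimulus grid while respecting the
    perceptual geometry of color space.  Implements Earth Mover's Distance
    (solved as a transportation problem by successive shortest paths) and the
    Quadratic Chi-squared histogram distance over CIELAB-76 Delta-E ground
    distances, an exponential chip-similarity kernel with a Cholesky
    de-correlation transform that makes classical statistics perceptually
    aware, matched-restart k-means clustering with stability reporting and a
    cluster hierarchy across k, parsers for World-Color-Survey-style response
    tables, and a seeded simulator of WCS-shaped naming data with known focal
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, png, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), boot, clue, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
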