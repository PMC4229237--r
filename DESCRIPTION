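Package: spamscal
Title: Individual-Differences Multidimensional Scaling for Spatial
    Arrangement Similarity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for converting spatial-arrangement (SpAM) similarity
    judgements and pairwise dissimilarity ratings into proximity matrices,
    fitting metric individual-differences weighted-Euclidean
    multidimensional scaling (INDSCAL-type) by alternating least squares
    with Kruskal stress-1 monitoring, deriving pair-similarity continua,
    item prototypicality classifications, subject "weirdness" scores and
    cross-dimensionality agreement curves, and validating scaling quality
    against Monte Carlo null models built from random screen arrangements
    or random Likert ratings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
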