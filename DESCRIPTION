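Package: mbgst
Title: Moment-Based Gene Set Tests
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene set enrichment testing against the self-contained null
    hypothesis using exact permutation moments of linear and quadratic test
    statistics instead of sampled permutations. Closed-form first, second and
    fourth permutation moments are matched to Gaussian, scaled-beta and
    scaled chi-squared reference distributions, yielding continuous p-values
    orders of magnitude faster than Monte Carlo permutation and free of
    permutation granularity. Includes exhaustive and Monte Carlo permutation
    oracles, rotation-sampling oracles for moment verification,
    experimental-design utilities (permutation granularity and the number of
    permutations required for a target power), GMT/expression/phenotype
    readers, Benjamini-Hochberg adjustment across sets, and a seedable
    synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
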