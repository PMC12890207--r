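Package: divbias
Title: Bias of Naive Diversification and Ancestral-Trait Estimators Under
    Incomplete Taxon Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reconstructed birth-death phylogenies with Brownian
    trait evolution and incomplete taxon sampling (uniform or clade-biased),
    applies the naive estimators sometimes used in comparative studies --
    log(n)/t clade rates, the Kendall-Moran speciation rate, tip "origin
    times" read off parent nodes, and interval-median ancestral trait
    values -- and quantifies their bias against simulation ground truth.
    Also provides the inverse-equal-splits (DR) tip-rate statistic and
    permutation tests of trait-rate association with tip-level and
    regime-level nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
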