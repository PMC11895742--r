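Package: stratpulse
Title: Extinction Pulse Detection and Proxy-Diversity Association for
    Stratigraphic Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of extinction dynamics across a bedded
    stratigraphic section. Builds a vetted fossil occurrence database over a
    bed/sub-bed column, computes stratigraphic ranges with classical
    uniform-recovery confidence intervals, and estimates the number and
    position of extinction pulses from last-appearance data under a
    Signor-Lipps missed-sampling model (likelihood over candidate horizons,
    BIC plus parametric-bootstrap likelihood-ratio selection, with an explicit
    continuous extinction-interval alternative). Geochemical proxy series are
    standardized to a common height datum, scaled between core and outcrop,
    aggregated to bed resolution, and imputed with continuous piecewise-linear
    (segmented) regression whose breakpoint count is selected by BIC.
    Proxy-diversity associations are quantified with a correlation screen,
    variance-inflation-factor model reduction, paired Poisson generalized
    linear models of species richness, and partial distance-based redundancy
    analysis of Jaccard incidence distances with permutation inference. A
    synthetic-data module generates occurrence, proxy and richness datasets
    with the assumed statistical structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    permute,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
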