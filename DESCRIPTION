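Package: vertiso
Title: Retrospective Stable-Isotope Chronologies from Vertebral Growth Bands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for retrospective stable-isotope analysis of sequentially
    sampled hard parts, developed around shark vertebral growth bands. Provides
    delta-value computation from raw isotope ratios, collagen C/N
    demineralization quality control, age-class chronology construction,
    a scaled (saturating) trophic-position model for delta-15N, birth-band
    relative enrichment series, Bayesian bivariate-normal isotopic niche
    metrics (standard ellipse areas, probabilistic niche regions, directional
    overlap and ellipse-intersection areas), an ontogenetic comparison battery
    (normality-gated parametric and non-parametric tests and isotope-age
    regressions), and a synthetic chronology generator so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
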