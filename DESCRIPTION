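Package: marsalt
Title: Saltation Transport and Abrasive Survival Bounds for Spores on Mars
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Couples an aeolian saltation hop-length model for wind-blown
    grains on Mars with spore-survival fractions measured under abrasive
    tumbling, to bound how far viable Bacillus subtilis endospores could
    travel before being sterilised by abrasion. Provides the hop-length
    formula with Mars defaults, a log-log interpolated survival curve
    anchored on digitized tumbling data plus a Weibull fit for
    extrapolation, deterministic linear (prevailing-wind) and random-walk
    (isotropic) travel-distance bounds with a Monte Carlo validator, a
    synthetic colony-count experiment generator with Poisson plating
    noise, and a pipeline reproducing the published travel-distance and
    survival table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
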