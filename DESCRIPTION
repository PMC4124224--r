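Package: ecoentropy
Title: Entropy-Weight Assessment of Regional Ecoenvironmental Vulnerability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Composite-indicator assessment of regional ecoenvironmental
    vulnerability with the improved entropy weight method: Z-score
    standardization of a regions-by-indicators decision matrix (population
    standard deviation), coordinate translation to strict positivity,
    Shannon information-entropy weighting with k = 1/ln(n), and a per-region
    composite vulnerability index with ranking.  Ships the western Jilin
    nine-region, ten-indicator worked example as a packaged fixture, a
    seeded synthetic decision-matrix generator for property testing, CSV and
    YAML/JSON readers and writers, amplitude sensitivity analysis, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
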