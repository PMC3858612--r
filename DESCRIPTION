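Package: dyadMove
Title: Kernel Home Ranges and Dynamic Interaction Analysis for Dyadic
    Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the spatial-social analysis of simultaneously
    radio-tracked animal dyads: fixed-kernel utilization distributions with
    ad hoc bandwidth selection, 95% isopleth home-range polygons,
    directional percent overlap, three dynamic-interaction tests (random
    gas encounter model, Hutchinson's instantaneous-sampling correction,
    Doncaster's contingency test), exact small-sample Wilcoxon tests,
    sleeping-association and social-interaction metrics, and a coupled
    Ornstein-Uhlenbeck movement simulator for validating every stage on
    study-shaped synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    MASS,
    polyclip,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
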