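Package: enorms
Title: Extrapolated Norms ('e-norms') Reference Intervals from Mixed Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives normative reference ranges from routinely collected
    clinical or laboratory data containing both healthy and pathological
    values, using the extrapolated-norms (e-norms) approach: measurements are
    sorted and plotted against rank, first-order differences are computed, and
    the low-difference "plateau" of the resulting curve is detected
    automatically and summarized into a normative range with distribution
    diagnostics. Includes age- and sex-stratified analysis, between-stratum
    comparisons, a contaminated-mixture cohort simulator for validation, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
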