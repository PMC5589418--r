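Package: tracemet
Title: Stable-Isotope Tracing Analysis for GC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 13C stable-isotope tracing experiments
    measured by GC-MS: natural-abundance correction of mass-isotopomer
    distributions for derivatized metabolite fragments, fractional-labeling
    and tracer-contribution statistics (including condition-contrast
    statistics such as the cystine-induced increase of glutamine
    contribution to alpha-ketoglutarate), exponential growth fitting and
    growth-normalized metabolite consumption/release rates, isotope-dilution
    absolute quantification against labeled internal standards, and a
    synthetic tracer-experiment generator with recorded ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
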