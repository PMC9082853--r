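Package: cistrans
Title: Empirical Cis/Trans Classification of Molecular QTLs from
    Variant-TSS Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies molecular quantitative trait loci (pQTLs, eQTLs,
    metabolite QTLs) into cis and trans regimes from the distribution of
    intrachromosomal variant to transcription-start-site distances. Fits a
    three-parameter mixture of a Weibull distribution on log10 distance
    (the distance-dependent cis component) and a parameter-free,
    chromosome-length-weighted random-pair distribution (the
    distance-independent trans component) to binned distance histograms by
    weighted nonlinear least squares, assesses fit by one-sample
    Kolmogorov-Smirnov tests, and locates the cross-over distance at which
    the two weighted densities are equal, with parametric-bootstrap
    confidence intervals. Includes readers and filters for study summary
    tables and a synthetic-data generator for the assumed mixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
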