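Package: flocscatter
Title: Fractal Dimension and Particle Size Analysis of Activated-Sludge Flocs from Static Light Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the structure of activated-sludge flocs
    (microbial aggregates) from static light scattering and laser granulometry.
    Provides a piecewise Guinier / power-law / Porod forward model of scattered
    intensity for fractal aggregates, automatic detection of the power-law
    (fractal) regime on log-log intensity curves, ordinary-least-squares
    estimation of the optical fractal dimension with Student-t confidence
    intervals, conversion of the fitted scattering-vector window into a
    particle-diameter range with Rayleigh-Gans-Debye validity flags, and
    particle-size-distribution utilities (volume/number basis conversion,
    range fractions, percentile diameters, size-band counts). A synthetic-data
    module generates calibrated size distributions, particle lists and noisy
    scattering curves with known ground truth so the whole pipeline can be
    exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
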