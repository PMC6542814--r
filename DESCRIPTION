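Package: photoloc
Title: Visual Modelling of Diurnal Active Photolocation in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiometric and psychophysical modelling of diurnal active
    photolocation: a fish redirects downwelling light from a bright iris
    spot ("ocular spark") onto the reflective eye of nearby micro-prey and
    reads back the coaxial reflection. The package provides spectral
    containers and CSV I/O, exact and Monte-Carlo solid angles of circular
    discs, the two-leg photon-flux model of the spark round trip, a
    receptor-noise-limited chromatic model and Michelson achromatic
    contrast for the viewer's visual system, detection-distance extraction
    over parameter sweeps, and a seeded synthetic-data generator that
    emulates the measured field and laboratory spectra so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
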