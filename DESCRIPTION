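Package: surfriction
Title: Interfacial Friction, Wetting and Energy Corrugation of Charged Model Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links surface charge heterogeneity to solid-water interfacial
    friction. Builds periodic charged model surfaces (hexagonal, square and
    rigid-CH2 lattices), maps the microscopic water-surface interaction
    energy landscape on a fine in-plane grid and its fluctuation statistic
    (the variance of E_micro over 0.25 A^2 cells), estimates the friction
    coefficient lambda from tangential-force autocorrelation via the
    Green-Kubo relation, extracts contact angles from droplet density
    fields by circle fitting of the liquid-vapor isodensity interface, and
    fits the linear lambda = zeta * (Delta E_micro)^2 model together with
    its q^2 charge scaling. Synthetic-data generators (Ornstein-Uhlenbeck
    force series, spherical-cap droplets, Boltzmann-sampled first-layer
    water) provide ground-truth inputs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
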