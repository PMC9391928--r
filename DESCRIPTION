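Package: aerostarch
Title: Airborne Starch Monitoring by Laser Spectroscopy: Classification,
    Calibration, Source Attribution and Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of an airborne-starch monitoring
    analysis as one reproducible pipeline. A seeded synthetic-campaign
    generator emulates co-located single-particle laser spectroscopy and
    Hirst-type volumetric sampling: multi-modal particle signals
    (scattering image, fluorescence spectrum, fluorescence lifetime),
    intermittent sub-hour starch emission episodes tied to a planted source
    bearing, a noisy reference sampler, and a 10 Hz wind record. On top of
    it the package provides a multi-input convolutional network classifier
    trained per signal modality, conversion of classified counts into
    number and mass concentrations with linear cross-calibration against
    the reference sampler, wind-rose source attribution from u/v wind
    components conditioned on high-starch hours, and a simplified
    Lagrangian Gaussian-puff dispersion model with lognormal particle sizes
    and gravitational settling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
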