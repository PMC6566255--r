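Package: pepperpot
Title: Vapour-Responsive Photonic Nanoarchitectures of Butterfly Wing Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the vapour-concentration-dependent reflectance of
    lycaenid butterfly wing scales coloured by "pepper-pot" photonic
    nanoarchitectures.  Provides direct-space averaging of cross-sectional
    TEM images, a parametric layered scale geometry with effective-medium
    optics, a transfer-matrix multilayer reflectance solver, whole-wing
    background and orientation-broadening corrections, a capillary
    condensation filling-and-swelling spectral mixing model, and
    least-squares recovery of filling and swelling parameters from relative
    reflectance series.  Seeded synthetic generators for TEM-like images and
    vapour spectra series make the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
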