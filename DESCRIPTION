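Package: gazediet
Title: Gaze Sampling and the Spectral Diet of Foveal Cones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the retinal cone-excitation input that single foveal
    cones receive while an observer's gaze roams a hyperspectral natural
    scene. Provides spectral and colorimetric primitives (cone excitations,
    CIE daylight illuminants, CAM16 cone-like responses and CAM16-UCS color
    differences), eccentricity-dependent retinal sampling, recorded and
    simulated gaze models (random gaze, fixed-step random walk, chromatic
    local-feature walk), the local-versus-global spectral-diet convergence
    statistic based on Freedman-Diaconis histograms and Pearson correlation,
    and the cumulative local von Kries adaptation analysis that tests how
    well local diagonal scaling discounts a global daylight illuminant
    change relative to global scaling. Includes seeded synthetic generators
    for scenes, illuminants and gaze traces so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
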