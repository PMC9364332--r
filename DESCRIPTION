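Package: kinagree
Title: Agreement Analysis for Wearable and Optical Shoulder Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates active shoulder movement trials observed by two
    imperfect measurement systems (a wearable inertial sensor and an
    optical motion-capture reference), extracts kinematic outcomes
    (range of motion, total range of motion, peak and mean angular
    velocity) from XZ'Y'' Euler-angle time series, and quantifies
    between-system agreement with Bland-Altman bias and limits of
    agreement, two-way mixed intraclass correlation, and root mean
    square error. Includes movement-phase segmentation, resampling and
    synchronization utilities, configurable measurement error models
    (offset, misalignment, amplitude scaling, drift, noise), and a
    reproducible end-to-end pipeline with plain-text file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
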