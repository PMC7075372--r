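Package: rtshift
Title: Automated Couch-Shift Instructions and User-Origin QA for
    Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R:
    person("rtshift", "maintainers", email = "rtshift@example.org",
           role = c("aut", "cre"))
Description: Vendor-neutral re-implementation of two treatment-planning
    quality-assurance tools used in radiation oncology. The first computes
    couch-shift instructions from the plan's user origin (the CT simulation
    marks) to the beam isocenter, applying a patient-orientation-aware
    transformation from the DICOM patient coordinate system to the IEC 61217
    fixed frame, and renders them as a printable "Treat Sheet" with values
    hardcoded to centimeters. The second verifies that the user origin was
    placed at the intersection of the three radiopaque simulation marker
    contours and flags plans that deviate beyond a set tolerance. Includes a
    minimal DICOM RT Plan / RT Structure Set / CT reader-writer (explicit VR
    little endian), a synthetic-fixture generator with known ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
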