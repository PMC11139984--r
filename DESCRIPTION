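Package: gridcut
Title: Grid-Cutting Removal of Soft Tissue from 3D Dental Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated soft-tissue removal from intraoral 3D dental photo
    scans by the grid-cutting method: the scan is oriented occlusal-side up,
    an occlusal plane is approximated by least-squares fitting through four
    cusp-representative points, an xy-grid of user-defined square size is laid
    over the arch, and each grid square is cropped independently so that only
    surface within a set distance of the square's highest point (toward the
    occlusal plane) is kept. Includes STL input/output with vertex welding, a
    labelled synthetic dental-arch generator for testing (missing teeth,
    partly erupted third molars, retromolar flaps), crop-quality metrics, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
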