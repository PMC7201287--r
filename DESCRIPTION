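Package: stem4d
Title: Sparse 4D-STEM Nanobeam Electron Diffraction Data Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for scanning nanobeam electron-diffraction
    tomography (nanoEDT) experiments built on sparse 4D-STEM acquisitions.
    Converts raw integrating-detector frames into hybrid electron counts,
    reconstructs virtual dark-field images, segments crystal regions in scan
    space, assembles region-selected diffraction tilt series exportable as SMV
    images, maps crystal thickness with the log-ratio model, and localizes
    Bragg peaks by binned circular-template matching. Includes a seeded
    synthetic 4D-STEM simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
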