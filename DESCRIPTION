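Package: cliftcad
Title: Automated Classification of Crithidia luciliae Immunofluorescence Test Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for the Crithidia luciliae
    immunofluorescence test (CLIFT) used to detect anti-dsDNA antibodies.
    Candidate kinetoplast regions are detected by robust intensity
    thresholding, candidate-bearing cells are localized and described by
    intensity-histogram, gray-level co-occurrence, Fourier, circular local
    binary pattern and morphological features, individual cells are classified
    by a kernel support vector machine, and labels are aggregated by majority
    voting from cells to images to wells with a reject (suspension) rule on
    tied wells. Includes a synthetic fluorescence-image generator with ground
    truth at well, image and cell level, a one-well-out cross-validation
    harness, contingency-table based evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
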