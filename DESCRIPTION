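Package: epicount
Title: Automated Counting of Leaf Epidermal Cells in Contact Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and counts leaf epidermal cells in light micrographs of
    fresh leaves pressed against glass, where only the convex cell-glass contact
    footprints are in focus. Implements a six-stage image-processing pipeline
    (red-channel extraction, Gaussian smoothing, minimum-method histogram
    auto-thresholding, iterated binary morphology, Euclidean distance transform,
    and noise-tolerance local-maxima detection), with all operator parameters
    derived from the pixel size in micrometres and the cell footprint shape
    class. Includes a synthetic epidermis micrograph generator with known ground
    truth, marker-matching validation utilities, per-image cell density and mean
    cell size reports, and batch command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
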