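Package: cellafe
Title: Automatic Feature Extraction and Neuro-Fuzzy Classification of
    Single-Cell Cervical Cytology Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments single-cell cervical cytology images into nucleus,
    cytoplasm and background and classifies them as normal, LSIL or HSIL.
    Grey-level cluster centres are found with moving k-means clustering and
    converted to two segmentation thresholds; the nucleus seed is located by
    seed-based region growing from the image corner followed by an
    image-moment centroid; a modified seed-based region growing pass then
    produces the tri-level segmentation mask while simultaneously extracting
    six morphological features (size, perimeter and mean grey level of the
    nucleus and cytoplasm). Classification uses a multiple adaptive
    neuro-fuzzy inference system (MANFIS): three parallel first-order Sugeno
    ANFIS models trained by hybrid least-squares / backpropagation learning.
    Includes a synthetic single-cell image generator with exact ground truth,
    a five-fold cross-validation harness with per-class accuracy reports, and
    a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
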