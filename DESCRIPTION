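Package: eagseg
Title: Enhanced Area Growth Segmentation of Lung Tumours on CT
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seeded region growing for lung tumour delineation on 2D CT
    slices and 3D volumes.  Implements a braided (level-synchronous)
    area-growth kernel with a per-level updated comparison intensity,
    automatic local Otsu thresholding around the primary tumour,
    lung-field masking, multi-start growth with radial boundary
    interpolation, and rule-gated edge refinement.  Ships a parametric
    chest-phantom simulator with exact ground truth, overlap metrics
    (Dice, recall, precision), readers and writers for PNG, TIFF, NIfTI
    and uncompressed DICOM, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
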