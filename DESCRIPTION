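Package: glcmfusion
Title: Volumetric GLCM Texture Features and LSTM Fusion for Lung Nodule
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based analysis of lung nodules in chest CT. Implements
    multi-level Otsu threshold segmentation accelerated by the water strider
    optimization algorithm (WSA-Otsu), gray-level co-occurrence matrix (GLCM)
    computation in 2D (8 directions per slice), 2.5D (per-slice stacks across
    a scan) and 3D (13 directions over contiguous volume spaces), Haralick
    texture descriptors, and a recurrent (LSTM) fusion classifier that
    combines the per-slab texture matrices into benign / malignant /
    ambiguous calls. Includes volume I/O (NIfTI, a minimal DICOM codec, and a
    packed-array container), preprocessing (Hounsfield windowing, median
    filtering, isotropic resampling), one-vs-rest multiclass evaluation
    metrics, seeded synthetic phantom generators for fully self-contained
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
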