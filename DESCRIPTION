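Package: lungbiopsy
Title: Computational-Biopsy Densitometry for Murine Lung Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automated densitometric analysis of murine thorax
    micro-CT stacks. Locates the middle-of-lung slices, detects breastbone
    and spine landmarks, places two cylindrical "computational biopsy"
    regions of interest inside the chest cavity, excludes airway voxels,
    and computes histogram features (mean lung attenuation, median, mode,
    full width at half maximum, skewness, kurtosis, and the
    normal-vs-fibrotic AUC ratio) that track disease severity in fibrosis,
    emphysema and LPS models. Includes a synthetic thorax-phantom
    generator with voxel-level ground truth so the whole pipeline can be
    exercised and validated without animal data, plus a legacy
    threshold-based segmentation mode that reproduces the density
    truncation artifact of semi-automated tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
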