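Package: bonespectq
Title: Quantitative Bone SPECT/CT Lesion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of bone SPECT/CT lesions: voxelwise
    standardized uptake value (SUV) mapping from activity concentration,
    semi-automatic histogram-threshold volume-of-interest segmentation,
    volumetric uptake metrics (metabolic bone volume, total bone uptake)
    with control-normalized ratios, and nonparametric comparison of those
    metrics across clinical stages (Kruskal-Wallis with tie correction and
    Steel-Dwass all-pairs post hoc). Includes a digital-phantom simulator
    with known ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
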