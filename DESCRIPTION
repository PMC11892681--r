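Package: msipd
Title: Mass Spectrometry Imaging Pharmacodynamics: Spatial Metabolic Response Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Pipeline for mapping heterogeneous tumour pharmacodynamic response
    from mass spectrometry imaging (MSI) data: imzML reading and writing,
    interpolation rebinning, root-mean-square spectrum normalisation, gradient
    peak detection on experiment mean spectra, accurate-mass adduct annotation,
    cross-experiment consensus peak matching, vehicle-normalised log2
    fold-change statistics, metabolite-driven pixel segmentation (exact t-SNE
    plus k-means), and landmark affine registration of MSI segmentations onto
    imaging mass cytometry (IMC) marker images with per-region cell-level
    quantification. Includes a seeded synthetic multi-experiment study
    generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
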