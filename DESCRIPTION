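Package: l3comp
Title: Multi-Slice L3 CT Body-Composition Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how body-composition measures taken from a
    single mid-L3 abdominal CT slice differ from measures taken across the
    whole L3 vertebral level. Provides a minimal DICOM reader/writer for axial
    CT slices, Hounsfield-unit threshold segmentation of skeletal muscle,
    visceral and subcutaneous adipose tissue with morphological
    visceral/subcutaneous compartment separation, per-slice surface area and
    radiodensity measures, a per-patient average-percent-difference statistic
    with sex-stratified Mann-Whitney comparison (exact and asymptotic), a
    parametric CT phantom generator with analytic ground truth, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
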