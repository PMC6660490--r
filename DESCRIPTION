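Package: dixonac
Title: Artifact Simulation and Correction for Segmented MR-Based
    Attenuation Maps in Cardiac PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital thorax phantoms and a slice-by-slice PET simulation
    pipeline for studying how artifacts in four-class (background, lung,
    fat, soft tissue) MR-derived attenuation-correction maps bias
    myocardial PET quantification. Provides injectors for the common
    artifact classes (susceptibility voids near sternal wires and
    implants, tissue inversions, photopenic diaphragm bands, truncation,
    respiratory misalignment), correction operators (six-neighbour
    majority-vote gap filling, rigid re-alignment against the
    non-attenuation-corrected reconstruction, truncation completion),
    OSEM reconstruction with attenuation factors in the system model,
    and a quantitation chain: relative-difference maps, 42%-threshold
    myocardial statistics, lung-volume test-retest metrics, and
    simplified 17-segment polar-map scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
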