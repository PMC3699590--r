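Package: atlaskit
Title: Population Template Construction and Atlas-Based Brain Parcellation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds average-shape, average-intensity population templates and
    probabilistic region atlases from sets of labeled 3-D MRI volumes, and uses
    them for automatic parcellation of new volumes by registration and
    maximum-probability labeling. Includes multiresolution block-matching
    elastic registration, mutual-information affine registration, majority-vote
    label fusion for delineation bootstrapping, diffusion-tensor estimation
    with FA/MD and color maps, Dice/confusion-matrix evaluation, and a
    synthetic labeled-phantom population generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
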