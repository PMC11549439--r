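Package: olfstereo
Title: Serial-Section Reconstruction and Stereology of the Olfactory
    Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for reconstructing and quantifying a
    serially sectioned olfactory en-bloc specimen from multi-channel
    fluorescence sections. Provides a synthetic virtual-specimen generator
    with exact ground truth; a compact U-Net semantic segmenter (one model
    per anatomical structure) with Dice-optimal threshold selection;
    Dice-guided block-wise registration (rigid plus B-spline free-form
    deformation, intensity pre-registration followed by mask-based
    refinement, and linear interpolation of interface displacement fields);
    and the stereological quantification chain: voxel-count volumes with
    interpolation over missing sections, the morphologically closed
    olfactory-epithelium envelope, Abercrombie-corrected olfactory sensory
    neuron densities, Fieller and delta-method error propagation,
    sphere-model glomerulus estimates, and interleaved-sampling error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
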