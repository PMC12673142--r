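Package: retinareg
Title: Curvature-Corrected Registration of Retinal OCT Surface Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Aligns a diagnostic (microscope-integrated) optical coherence
    tomography (OCT) retinal surface with sparse instrument-integrated OCT
    (iiOCT) distance measurements acquired by an intraocular robot.
    Implements first-reflection surface segmentation, probe-pose point
    reconstruction, geometric least-squares sphere fitting, a fovea-anchored
    curvature-correction deformation field, landmark-based initial alignment,
    point-to-plane iterative closest point and nonrigid coherent point drift
    fine registration, robotic scan-trajectory generation with a
    velocity-frequency timing model, and validation metrics (mean fiducial
    marker error and cylinder-cropped Chamfer distance). A synthetic eye
    phantom generator with known ground truth supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'curvature.R'
    'evaluate.R'
    'extract.R'
    'io.R'
    'phantom.R'
    'trajectory.R'
    'register.R'
    'pipeline.R'
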