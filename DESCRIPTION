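Package: afmrigid
Title: Rigid-Body Fitting of Atomic Structures to AFM Images with
    Probe-Shape Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustive-search rigid-body fitting of atomic structures to
    atomic force microscopy (AFM) height maps.  Pseudo-AFM images are
    generated from an atomic model by collision detection against a
    parametric probe tip (a hemisphere capped by a cone frustum), scored
    against a reference image with one of four cost functions (cosine
    similarity, correlation coefficient, pixel-RMSD, or a penalty
    function), and the molecular orientation, XY translation, Z offset and
    probe-tip geometry are searched simultaneously on a discrete grid.
    Includes a twin-experiment validation harness with synthetic
    ground-truth generators, stage-plane estimation and background-noise
    statistics for experimental height maps, and blind tip reconstruction
    by mathematical morphology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
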