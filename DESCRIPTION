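Package: vfsim
Title: Visual Field Boundary Simulation from Parametric Head Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the anatomical visual field of a human eye by ray casting
    against triangle meshes of the head. Provides blendshape synthesis of novel
    head shapes from a morphable model, an eye-centered five-camera cube rig with
    exact binary visibility, extraction of the visual field boundary theta(phi)
    from occlusion maps, projected-solid-angle metrics, linear prediction of
    boundaries from shape coefficients, and weighted least-squares optimization of
    boundary templates with gradient descent and a closed-form oracle. Includes a
    deterministic synthetic morphable-head generator and analytic occluder
    fixtures so the full pipeline runs without external mesh assets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
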