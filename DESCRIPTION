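Package: wingmorph
Title: Morphometrics and Continuum Modeling of Epithelial Convergent Extension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of planar epithelial morphogenesis in the
    style of Drosophila pupal wing studies: triangulation-based nematic
    cell-elongation tensors, decomposition of tissue shear into cell-shape
    change and cellular rearrangements, detection of T1/T2/rosette events on
    tracked cell meshes, watershed segmentation of membrane-marker images,
    junctional polarity and surface-coverage metrics, and an active continuum
    model of autonomous tissue elongation with a grid-based least-squares
    parameter fit. Ships a synthetic-epithelium generator (Voronoi meshes,
    kinematically imposed shear, planted rearrangement events, rendered
    membrane images, model-generated elongation curves) so the whole pipeline
    is testable end to end without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    deSolve,
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    expm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
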