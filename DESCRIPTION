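Package: neckmatch
Title: Comparative Connectomics of Neck-Connective Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparative analysis of neurons crossing the neck
    connective between the insect brain and ventral nerve cord. Implements
    morphological matching of neurons across hemispheres and electron-
    microscopy datasets (NBLAST scoring on dotprops, mirroring, thin-plate-
    spline landmark registration), rule-based anatomical annotation (soma
    side, brain and nerve-cord neuropil codes, longitudinal tract
    assignment), sensory information-flow ranking over the synaptic graph,
    thresholded connectivity analysis with stereotypy statistics, and
    classification of sex-specific versus sexually dimorphic cell types.
    Ships a deterministic synthetic-connectome generator with planted ground
    truth so every stage of the pipeline can be validated end to end without
    external data services.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
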