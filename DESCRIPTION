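Package: neurovasc
Title: Simulation and Quantitative Analysis of Neurovascular MRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cerebrovascular function from multimodal
    MRI in ageing cohorts: perfusion and BOLD responses to block-design visual
    stimulation from dual-echo pseudo-continuous arterial spin labelling
    (pCASL) via voxel-wise general linear models and z-thresholded cluster ROI
    selection; global cerebral blood flow from phase-contrast velocity maps;
    venous oxygen saturation from susceptibility-based dual-echo phase
    oximetry and Fick-principle cerebral metabolic rate of oxygen; breath-hold
    cerebrovascular reactivity with a cohort-mean regressor; lactate and
    N-acetylaspartate quantification from long-echo-time MR spectra; and a
    cohort statistics layer (robust regression, false-discovery-rate
    correction, stepwise model selection, attrition accounting). A fully
    synthetic cohort generator with known ground truth emulates every input
    modality so the entire pipeline is testable end to end without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
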