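Package: spinedyn
Title: Functional Synaptic Connectivity and Dendritic Spine Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic two-photon calcium imaging of
    dendritic spines under optogenetic presynaptic stimulation. Detects
    optogenetically evoked excitatory postsynaptic calcium transients
    (EPSCaTs) in spine and dendrite fluorescence traces with permutation
    nulls, classifies spines as responsive or unresponsive across imaging
    sessions, computes longitudinal spine-dynamics statistics (survival
    sequences, turnover ratio, survival fraction, lifetime, density),
    estimates spine head volumes from labelled projection images and
    dendritic path distances on skeleton graphs, and provides
    seed-deterministic permutation tests and mixed-model wrappers for group
    comparisons. Includes a ground-truth-annotated synthetic experiment
    generator so the whole pipeline is testable without imaging data.
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
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    lme4,
    lmerTest,
    readr,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
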