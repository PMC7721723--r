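Package: airwaymorph
Title: Upper Airway Morphometry, Airflow Simulation and Respiratory Analysis for Mouse Micro-CT Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for upper-airway phenotyping in mouse models of
    craniofacial disease: airway lumen segmentation from volumetric micro-CT images
    (intensity inversion plus thresholding), centerline-anchored perpendicular
    cross-sectional morphometry, craniofacial landmark-distance batteries with
    hyoid-position metrics, steady incompressible airflow simulation (quasi-1D
    Bernoulli-Poiseuille and 3D voxel-grid projection solvers) with segment-wise
    pressure decomposition, whole-body plethysmography breath analysis, and Welch
    two-sample inference from raw samples or published summary statistics. Includes
    a synthetic phantom generator (tubes, venturi constrictions, parametric mouse
    upper airways, breathing traces, two-group morphometry cohorts) with analytic
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
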