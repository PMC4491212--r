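Package: surfmorph
Title: Vertex-Wise Surface Morphometry with Cluster Inference, Stability
    and Power Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-univariate group analysis of cortical surface
    morphometry (vertex-wise cortical volume, thickness and local
    gyrification index). Provides matched case-control quartet
    construction across acquisition sites, vertex-wise general linear
    models with factorial sex/diagnosis designs and covariates,
    Monte-Carlo cluster-extent correction on triangulated surface
    meshes, bootstrap subsampling stability analysis over matched
    quartets, and effect-size-based achieved-power and required-sample
    -size computation. Includes a synthetic cohort generator that
    emulates a multi-site autism case-control study (sex-scaled global
    brain volumes, site offsets, spatially smooth vertex noise and
    planted effect clusters with specified Cohen's f) so that every
    stage of the pipeline is testable end to end without access to
    restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
biocViews: StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
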