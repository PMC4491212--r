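#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats pnorm qnorm pf qf pt rnorm runif sd var aov TukeyHSD
#'   t.test complete.cases setNames quantile median uniroot ks.test ave
#' @importFrom utils read.csv write.csv read.table write.table head
NULL

#' Triangulated surface mesh
#'
#' Stand-in for a registered cortical hemisphere surface: vertex
#' coordinates in mm, triangular faces, per-vertex areas (one third of
#' the incident triangle areas, mm^2), an undirected adjacency list and
#' the mean edge length.  Statistics downstream depend only on areas,
#' adjacency and smoothness, so an area-calibrated icosphere (see
#' [buildMesh()]) is an adequate geometric substrate.
#'
#' @slot coords numeric matrix, n x 3, vertex positions (mm).
#' @slot faces integer matrix, m x 3, triangle vertex indices.
#' @slot vertexArea numeric, per-vertex area in mm^2.
#' @slot adjacency list of integer vectors, neighbours per vertex.
#' @slot meanEdgeLength numeric scalar, mm.
#' @slot smoothOp sparse one-step diffusion operator (dgCMatrix).
#' @slot id character digest identifying the mesh.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(
    coords = "matrix",
    faces = "matrix",
    vertexArea = "numeric",
    adjacency = "list",
    meanEdgeLength = "numeric",
    smoothOp = "ANY",
    id = "character"
  )
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  nv <- nrow(object@coords)
  if (length(object@vertexArea) != nv)
    msg <- c(msg, "vertexArea length must equal vertex count")
  if (any(object@vertexArea <= 0))
    msg <- c(msg, "all vertex areas must be positive")
  tri <- triangleAreas(object@coords, object@faces)
  if (abs(sum(object@vertexArea) - sum(tri)) > 1e-6 * sum(tri))
    msg <- c(msg, "vertex areas must sum to total triangle area")
  # adjacency symmetry (spot-check all edges)
  for (i in seq_len(min(nv, length(object@adjacency)))) {
    for (j in object@adjacency[[i]]) {
      if (!(i %in% object@adjacency[[j]])) {
        msg <- c(msg, "adjacency must be symmetric")
        break
      }
    }
    if (length(msg) && msg[length(msg)] == "adjacency must be symmetric")
      break
  }
  if (!meshConnected(object@adjacency))
    msg <- c(msg, "mesh must be connected")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic multi-site cohort
#'
#' Holds every generator parameter: group sizes, site list and
#' weights, the age distribution, sex-scaled global-volume anchors,
#' volume component shares, site offsets, vertex-noise level and
#' smoothness, covariate slopes and the planted effect clusters.
#' Defaults emulate the multi-site autism cohort the package is
#' modelled on (see the vignette).
#'
#' @slot groupSizes named integer, subjects per ASD_F/ASD_M/TD_F/TD_M.
#' @slot sites character vector of site labels.
#' @slot siteWeights sampling weight per site.
#' @slot ageMean,ageSD,ageRange age distribution (years), truncated normal.
#' @slot volMeans,volSDs named numeric, supratentorial volume (cm^3)
#'   mean/SD per group.
#' @slot volShares named numeric, cortical/white/subcortical shares of
#'   the supratentorial volume (sum to 1, sex-independent).
#' @slot shareJitterSD SD of per-subject share perturbation.
#' @slot fsiqMeans,fsiqSDs named numeric per group.
#' @slot siteOffsetSD SD of the scalar per-site vertex offset.
#' @slot noiseSD per-vertex noise SD (metric units).
#' @slot noiseFWHM target smoothness of the vertex noise field (mm).
#' @slot betaAge,betaCV covariate slopes (metric units per year, per cm^3).
#' @slot effectClusters list of effect-cluster descriptors
#'   (seedVertex, targetArea cm^2, metric, effectType, cohensF, direction).
#' @slot matched logical; TRUE generates quartet-linked sites and ages.
#' @slot ageJitterSD within-quartet age jitter (years) in matched mode.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    groupSizes = "integer",
    sites = "character",
    siteWeights = "numeric",
    ageMean = "numeric", ageSD = "numeric", ageRange = "numeric",
    volMeans = "numeric", volSDs = "numeric",
    volShares = "numeric", shareJitterSD = "numeric",
    fsiqMeans = "numeric", fsiqSDs = "numeric",
    siteOffsetSD = "numeric",
    noiseSD = "numeric", noiseFWHM = "numeric",
    betaAge = "numeric", betaCV = "numeric",
    effectClusters = "list",
    matched = "logical", ageJitterSD = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (any(object@groupSizes < 0)) msg <- c(msg, "group sizes must be >= 0")
  if (!identical(sort(names(object@groupSizes)),
                 sort(c("ASD_F", "ASD_M", "TD_F", "TD_M"))))
    msg <- c(msg, "groupSizes must be named ASD_F/ASD_M/TD_F/TD_M")
  if (length(object@sites) == 0 && sum(object@groupSizes) > 0)
    msg <- c(msg, "site list may not be empty for a nonempty cohort")
  if (length(object@siteWeights) != length(object@sites))
    msg <- c(msg, "one sampling weight per site required")
  if (object@noiseFWHM < 0) msg <- c(msg, "noise FWHM must be >= 0")
  if (abs(sum(object@volShares) - 1) > 1e-8)
    msg <- c(msg, "volume shares must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Subject-by-vertex morphometry container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with vertices as rows
#' and subjects as columns; one assay per metric (\code{volume},
#' \code{thickness}, \code{lgi}).  The phenotype table is the
#' \code{colData}; the mesh, the generating [CohortSpec-class] and the
#' planted truth masks live in \code{metadata()}.
#'
#' @exportClass VertexExperiment
setClass("VertexExperiment", contains = "SummarizedExperiment")

setValidity("VertexExperiment", function(object) {
  msg <- character()
  mesh <- S4Vectors::metadata(object)$mesh
  if (!is(mesh, "SurfaceMesh"))
    msg <- c(msg, "metadata(object)$mesh must be a SurfaceMesh")
  else if (nrow(object) != nrow(mesh@coords))
    msg <- c(msg, "row count must equal mesh vertex count")
  for (a in SummarizedExperiment::assayNames(object)) {
    if (any(!is.finite(SummarizedExperiment::assay(object, a))))
      msg <- c(msg, sprintf("assay '%s' contains non-finite values", a))
  }
  if (length(msg)) msg else TRUE
})

#' Model design for the vertex-wise GLM and the global ANCOVAs
#'
#' Effect-coded (+/-1) sex and diagnosis factors plus their product,
#' with mean-centred covariates.  `term` names the factor whose
#' extra-sum-of-squares F is reported.
#'
#' @slot term one of "sex", "diagnosis", "interaction".
#' @slot covariates ordered subset of
#'   c("age", "cortical_vol", "site", "fsiq").
#' @exportClass DesignSpec
setClass("DesignSpec",
  representation(term = "character", covariates = "character"))

setValidity("DesignSpec", function(object) {
  ok <- c("sex", "diagnosis", "interaction")
  okc <- c("age", "cortical_vol", "site", "fsiq")
  msg <- character()
  if (!(object@term %in% ok))
    msg <- c(msg, "term must be sex, diagnosis or interaction")
  if (length(object@covariates) && !all(object@covariates %in% okc))
    msg <- c(msg, "covariates must be among age/cortical_vol/site/fsiq")
  if (length(msg)) msg else TRUE
})

#' Result of a vertex-wise GLM fit
#'
#' @slot statF,p,tSigned,effectF per-vertex maps: extra-sum-of-squares
#'   F for the term of interest, its two-sided p, the signed t
#'   (single-df terms) and the partial Cohen's f = sqrt(F*df1/df2).
#' @slot coefficients parameter-by-vertex matrix.
#' @slot residualMaps vertex-by-subject residual matrix.
#' @slot df1,df2 numerator/denominator degrees of freedom.
#' @slot term,metric character labels.
#' @slot design the [DesignSpec-class] used.
#' @slot nSubjects integer.
#' @exportClass VertexGLM
setClass("VertexGLM",
  representation(
    statF = "numeric", p = "numeric", tSigned = "numeric",
    effectF = "numeric", coefficients = "matrix",
    residualMaps = "matrix", df1 = "numeric", df2 = "numeric",
    term = "character", metric = "character", design = "DesignSpec",
    nSubjects = "integer"
  )
)

setValidity("VertexGLM", function(object) {
  msg <- character()
  if (any(object@p <= 0 | object@p > 1)) msg <- c(msg, "p must lie in (0,1]")
  if (any(object@effectF < 0)) msg <- c(msg, "effect sizes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Suprathreshold clusters on a surface mesh
#'
#' @slot clusters list; each element has vertices (integer), area
#'   (cm^2), peak (vertex index), peakStat, sign (+1/-1) and
#'   clusterwiseP (NA until [assignClusterwiseP()]).
#' @slot meshId character.
#' @slot formingP the cluster-forming (vertex-level) p threshold.
#' @slot smoothness FWHM (mm) of the map the clusters came from, if known.
#' @exportClass SurfaceClusters
setClass("SurfaceClusters",
  representation(clusters = "list", meshId = "character",
                 formingP = "numeric", smoothness = "numeric"))

#' Monte-Carlo null distribution of maximal cluster extent
#'
#' @slot maxAreas sorted maximal suprathreshold cluster areas (cm^2),
#'   one per simulated smooth null map.
#' @slot nSims number of simulations (>= 100).
#' @slot formingP cluster-forming p threshold used.
#' @slot smoothness FWHM (mm) of the simulated fields.
#' @slot meshId character.
#' @slot seed integer seed used.
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(maxAreas = "numeric", nSims = "integer",
                 formingP = "numeric", smoothness = "numeric",
                 meshId = "character", seed = "integer"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (object@nSims < 100L) msg <- c(msg, "at least 100 simulations required")
  if (any(object@maxAreas < 0)) msg <- c(msg, "areas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bootstrap subsampling stability result
#'
#' @slot sizes per-group sample sizes examined.
#' @slot nBoot bootstrap replicates per size.
#' @slot detection sizes-by-reference-clusters matrix of detection
#'   frequencies in [0,1].
#' @slot freqMaps vertex-by-sizes matrix: per-vertex fraction of
#'   replicates significant at the configured threshold.
#' @slot alpha,formingP thresholds used.
#' @slot corrected logical; TRUE = cluster-corrected counting.
#' @slot referenceClusters the full-cohort [SurfaceClusters-class].
#' @slot seed master seed.
#' @exportClass StabilityResult
setClass("StabilityResult",
  representation(sizes = "integer", nBoot = "integer",
                 detection = "matrix", freqMaps = "matrix",
                 alpha = "numeric", formingP = "numeric",
                 corrected = "logical",
                 referenceClusters = "SurfaceClusters",
                 seed = "integer"))

setValidity("StabilityResult", function(object) {
  msg <- character()
  if (any(object@detection < 0 | object@detection > 1))
    msg <- c(msg, "detection frequencies must lie in [0,1]")
  if (any(object@freqMaps < 0 | object@freqMaps > 1))
    msg <- c(msg, "frequency maps must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Calibrated effect-size/sample-size power model
#'
#' Normal-approximation power for a single-df factorial contrast with
#' noncentrality lambda = f^2 * N: power(N) = Phi(f*sqrt(N) - zCrit).
#' `zCrit` is calibrated from an anchor (f, N, power) triple rather
#' than from a nominal alpha.  An exact noncentral-F mode is available
#' via [achievedPower()].
#'
#' @slot f Cohen's f the model was anchored with.
#' @slot zCrit calibrated critical deviate.
#' @slot mode "normal" or "exactF".
#' @slot alphaImplied two-sided alpha implied by zCrit.
#' @slot anchorN,anchorPower the calibration anchor.
#' @slot rankAdjust residual-df adjustment (model rank) in exact mode.
#' @exportClass PowerModel
setClass("PowerModel",
  representation(f = "numeric", zCrit = "numeric", mode = "character",
                 alphaImplied = "numeric", anchorN = "numeric",
                 anchorPower = "numeric", rankAdjust = "numeric"))

setValidity("PowerModel", function(object) {
  if (object@zCrit <= 0) "calibrated critical deviate must be positive"
  else TRUE
})
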