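#' @rdname SurfaceMesh-class
#' @param x,object a \code{SurfaceMesh}.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("vertexAreas", function(x) standardGeneric("vertexAreas"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshAdjacency", function(x) standardGeneric("meshAdjacency"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meanEdgeLength", function(x) standardGeneric("meanEdgeLength"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshId", function(x) standardGeneric("meshId"))

#' @rdname VertexExperiment-class
#' @param x a \code{VertexExperiment}.
#' @export
setGeneric("vxMesh", function(x) standardGeneric("vxMesh"))

#' @rdname VertexExperiment-class
#' @export
setGeneric("truthMasks", function(x) standardGeneric("truthMasks"))

#' @rdname VertexExperiment-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname SurfaceClusters-class
#' @param x a \code{SurfaceClusters}.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname SurfaceClusters-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname StabilityResult-class
#' @param x a \code{StabilityResult}.
#' @export
setGeneric("detectionTable", function(x) standardGeneric("detectionTable"))

# ---- accessors -------------------------------------------------------

#' @rdname SurfaceMesh-class
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@coords))

#' @rdname SurfaceMesh-class
#' @export
setMethod("vertexAreas", "SurfaceMesh", function(x) x@vertexArea)

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshAdjacency", "SurfaceMesh", function(x) x@adjacency)

#' @rdname SurfaceMesh-class
#' @export
setMethod("meanEdgeLength", "SurfaceMesh", function(x) x@meanEdgeLength)

#' @rdname SurfaceMesh-class
#' @export
setMethod("totalArea", "SurfaceMesh", function(x) sum(x@vertexArea))

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshId", "SurfaceMesh", function(x) x@id)

#' @rdname VertexExperiment-class
#' @export
setMethod("vxMesh", "VertexExperiment",
          function(x) S4Vectors::metadata(x)$mesh)

#' @rdname VertexExperiment-class
#' @export
setMethod("truthMasks", "VertexExperiment",
          function(x) S4Vectors::metadata(x)$truthMasks %||% list())

#' @rdname VertexExperiment-class
#' @export
setMethod("phenotypes", "VertexExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname SurfaceClusters-class
#' @export
setMethod("nClusters", "SurfaceClusters", function(x) length(x@clusters))

#' @rdname SurfaceClusters-class
#' @export
setMethod("clusterTable", "SurfaceClusters", function(x) {
  if (!length(x@clusters)) {
    return(data.frame(cluster = integer(), area_cm2 = numeric(),
                      peak_vertex = integer(), peak_stat = numeric(),
                      sign = integer(), clusterwise_p = numeric()))
  }
  data.frame(
    cluster = seq_along(x@clusters),
    area_cm2 = vapply(x@clusters, `[[`, numeric(1), "area"),
    peak_vertex = vapply(x@clusters, `[[`, integer(1), "peak"),
    peak_stat = vapply(x@clusters, `[[`, numeric(1), "peakStat"),
    sign = vapply(x@clusters, `[[`, numeric(1), "sign"),
    clusterwise_p = vapply(x@clusters, function(cl)
      cl$clusterwiseP %||% NA_real_, numeric(1))
  )
})

#' @rdname StabilityResult-class
#' @export
setMethod("detectionTable", "StabilityResult", function(x) {
  df <- data.frame(size = x@sizes)
  cbind(df, as.data.frame(x@detection))
})

# ---- show methods ----------------------------------------------------

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf(
    "SurfaceMesh: %d vertices, %d faces, total area %.1f cm^2\n",
    nrow(object@coords), nrow(object@faces), sum(object@vertexArea) / 100))
  cat(sprintf("  mean edge length %.2f mm, id %s\n",
              object@meanEdgeLength, object@id))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = " "), "\n")
  cat(sprintf("  %d sites; age %.1f +/- %.1f (range %.0f-%.0f)\n",
              length(object@sites), object@ageMean, object@ageSD,
              object@ageRange[1], object@ageRange[2]))
  cat(sprintf("  vertex noise SD %.3g at %.1f mm FWHM; %d effect cluster(s)\n",
              object@noiseSD, object@noiseFWHM,
              length(object@effectClusters)))
})

setMethod("show", "VertexGLM", function(object) {
  cat(sprintf(
    "VertexGLM: term '%s' on metric '%s', %d subjects, df = (%g, %g)\n",
    object@term, object@metric, object@nSubjects, object@df1, object@df2))
  cat(sprintf("  min p = %.3g, max |f| = %.3f\n",
              min(object@p), max(object@effectF)))
})

setMethod("show", "SurfaceClusters", function(object) {
  cat(sprintf("SurfaceClusters: %d cluster(s) at forming p < %g\n",
              length(object@clusters), object@formingP))
  if (length(object@clusters)) print(clusterTable(object))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: %d sims, forming p %g, smoothness %.1f mm\n",
    object@nSims, object@formingP, object@smoothness))
  cat(sprintf("  max-area quantiles (cm^2): 50%% %.2f, 95%% %.2f, 99%% %.2f\n",
              quantile(object@maxAreas, 0.5),
              quantile(object@maxAreas, 0.95),
              quantile(object@maxAreas, 0.99)))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "StabilityResult: sizes %s, %d replicates, %s counting\n",
    paste(object@sizes, collapse = "/"), object@nBoot,
    if (object@corrected) "cluster-corrected" else "uncorrected"))
  print(detectionTable(object))
})

setMethod("show", "PowerModel", function(object) {
  cat(sprintf(
    "PowerModel (%s): f = %.3f, zCrit = %.3f (implied two-sided alpha %.4f)\n",
    object@mode, object@f, object@zCrit, object@alphaImplied))
  cat(sprintf("  anchored at power %.2f with total N = %g\n",
              object@anchorPower, object@anchorN))
})
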