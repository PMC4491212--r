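# Cluster-forming thresholding on the mesh and Monte-Carlo estimation
# of the null distribution of maximal suprathreshold cluster extent.

# Label connected components of `vertices` (integer set) under the
# mesh adjacency.  Returns a list of integer vectors.  Hand-rolled
# BFS: this sits in the hot loop of the null simulation and the
# bootstrap.
connectedComponents <- function(vertices, adjacency) {
  if (!length(vertices)) return(list())
  inSet <- logical(length(adjacency))
  inSet[vertices] <- TRUE
  seen <- logical(length(adjacency))
  comps <- list()
  for (v0 in vertices) {
    if (seen[v0]) next
    comp <- integer()
    stack <- v0
    seen[v0] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- adjacency[[v]]
      nb <- nb[inSet[nb] & !seen[nb]]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Extract suprathreshold clusters from a p map
#'
#' Connected components of vertices with p below the cluster-forming
#' threshold, with positive and negative effects clustered
#' separately.  Cluster areas are sums of member vertex areas (cm^2);
#' the peak is the member with the smallest p.
#'
#' @param pMap per-vertex two-sided p values.
#' @param signMap per-vertex signed statistic (only its sign is used).
#' @param mesh a [SurfaceMesh-class].
#' @param formingP cluster-forming p threshold (vertex level).
#' @param smoothness optional FWHM (mm) recorded for null matching.
#' @return a [SurfaceClusters-class] (empty when nothing survives).
#' @export
extractClusters <- function(pMap, signMap, mesh, formingP = 0.01,
                            smoothness = NA_real_) {
  stopIfNot(length(pMap) == nVertices(mesh),
            "p map length must equal mesh vertex count")
  clusters <- list()
  for (sgn in c(1, -1)) {
    sel <- which(pMap < formingP & sign(signMap) == sgn)
    for (comp in connectedComponents(sel, mesh@adjacency)) {
      peak <- comp[which.min(pMap[comp])]
      clusters[[length(clusters) + 1L]] <- list(
        vertices = comp,
        area = sum(mesh@vertexArea[comp]) / 100,
        peak = peak,
        peakStat = sgn * abs(signMap[peak]),
        sign = sgn,
        clusterwiseP = NA_real_)
    }
  }
  if (length(clusters)) {
    ord <- order(-vapply(clusters, `[[`, numeric(1), "area"))
    clusters <- clusters[ord]
  }
  new("SurfaceClusters", clusters = clusters, meshId = mesh@id,
      formingP = formingP, smoothness = smoothness)
}

# Maximal suprathreshold cluster area (cm^2) of a standardized map,
# both signs considered; 0 when nothing survives.
maxClusterArea <- function(z, mesh, formingP) {
  thr <- qnorm(formingP / 2, lower.tail = FALSE)
  out <- 0
  for (sgn in c(1, -1)) {
    sel <- which(sgn * z > thr)
    for (comp in connectedComponents(sel, mesh@adjacency)) {
      a <- sum(mesh@vertexArea[comp]) / 100
      if (a > out) out <- a
    }
  }
  out
}

#' Simulate the null distribution of maximal cluster extent
#'
#' Per simulation: a Gaussian white map is smoothed to the given
#' FWHM, standardized, converted to two-sided normal p values,
#' thresholded at the cluster-forming p and clustered; the maximal
#' cluster area is recorded.  Deterministic given `seed`.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param smoothness target FWHM in mm (below mesh resolution
#'   proceeds unsmoothed with a warning).
#' @param formingP cluster-forming p threshold.
#' @param nSims number of simulations (>= 100).
#' @param seed integer seed.
#' @param blockSize simulations per smoothing block (memory knob).
#' @return a [NullDistribution-class].
#' @export
simulateNull <- function(mesh, smoothness, formingP = 0.01,
                         nSims = 1000L, seed = 1L, blockSize = 250L) {
  stopIfNot(nSims >= 100L, "at least 100 simulations required")
  nv <- nVertices(mesh)
  unsmoothed <- smoothness < mesh@meanEdgeLength / 2
  if (unsmoothed)
    warning("smoothness below mesh resolution; simulating unsmoothed null")
  k <- if (unsmoothed) 0L else calibrateSmoothing(mesh, smoothness)
  W <- mesh@smoothOp
  maxAreas <- withSeed(seed, {
    out <- numeric(nSims)
    done <- 0L
    while (done < nSims) {
      nb <- min(blockSize, nSims - done)
      X <- matrix(rnorm(nv * nb), nv, nb)
      for (i in seq_len(k)) X <- W %*% X
      X <- as.matrix(X)
      X <- sweep(X, 2, colMeans(X), "-")
      X <- sweep(X, 2, sqrt(colSums(X^2) / (nv - 1)), "/")
      for (j in seq_len(nb))
        out[done + j] <- maxClusterArea(X[, j], mesh, formingP)
      done <- done + nb
    }
    out
  })
  new("NullDistribution", maxAreas = sort(maxAreas),
      nSims = as.integer(nSims), formingP = formingP,
      smoothness = smoothness, meshId = mesh@id,
      seed = as.integer(seed))
}

#' Assign cluster-wise p values from a Monte-Carlo null
#'
#' Uses the add-one estimator
#' p = (1 + #\{null maxima >= area\}) / (1 + nSims), which is monotone
#' nonincreasing in area and never exactly zero.  The null table must
#' match the clusters' mesh, forming threshold and smoothness (within
#' a 1 mm bin).
#'
#' @param clusters a [SurfaceClusters-class].
#' @param null a [NullDistribution-class].
#' @return the clusters with `clusterwiseP` filled in.
#' @export
assignClusterwiseP <- function(clusters, null) {
  stopIfNot(clusters@meshId == null@meshId,
            "null table was simulated on a different mesh")
  stopIfNot(isTRUE(all.equal(clusters@formingP, null@formingP)),
            "null table uses a different cluster-forming threshold")
  if (!is.na(clusters@smoothness) &&
      abs(clusters@smoothness - null@smoothness) > 1) {
    stop("null table smoothness differs by more than 1 mm",
         call. = FALSE)
  }
  clusters@clusters <- lapply(clusters@clusters, function(cl) {
    cl$clusterwiseP <-
      (1 + sum(null@maxAreas >= cl$area)) / (1 + null@nSims)
    cl
  })
  clusters
}

#' Serialize / load a null distribution with provenance
#'
#' @param null a [NullDistribution-class].
#' @param path JSON path.
#' @return `readNullDistribution` returns the object; the writer
#'   returns `path` invisibly.
#' @export
writeNullDistribution <- function(null, path) {
  jsonlite::write_json(
    list(max_areas = null@maxAreas, n_sims = null@nSims,
         forming_p = null@formingP, smoothness = null@smoothness,
         mesh_id = null@meshId, seed = null@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNullDistribution
#' @export
readNullDistribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NullDistribution", maxAreas = as.numeric(x$max_areas),
      nSims = as.integer(x$n_sims), formingP = x$forming_p,
      smoothness = x$smoothness, meshId = x$mesh_id,
      seed = as.integer(x$seed))
}

# Dice overlap of two vertex sets.
diceOverlap <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
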