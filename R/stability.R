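# Bootstrap subsampling stability analysis over matched quartets.

#' Bootstrap subsampling stability of cluster findings
#'
#' For each per-group sample size s and each bootstrap replicate, s
#' complete quartets are drawn without replacement, the vertex-wise
#' GLM and cluster inference are rerun on the 4s subjects, and two
#' things are recorded: whether each reference cluster is detected (a
#' significant same-sign cluster with Dice overlap > 0.25 against the
#' reference footprint), and the per-vertex significance indicator.
#' Replicate-level seeds are derived from the master seed by counter,
#' so any single replicate is reproducible in isolation.  At the full
#' complete-quartet count every replicate is the identical cohort, so
#' detection frequency is exactly 1 for clusters significant in the
#' full cohort.
#'
#' @param ve a [VertexExperiment-class].
#' @param quartets quartet table from [buildQuartets()]; only
#'   complete quartets are eligible.
#' @param design a [DesignSpec-class].
#' @param referenceClusters a [SurfaceClusters-class] of full-cohort
#'   significant clusters (the targets of detection).
#' @param null a [NullDistribution-class] shared across replicates
#'   (matched on mesh, forming threshold and smoothness bin).
#' @param sizes per-group sample sizes (default 15 to 50 in steps of
#'   5, the published grid).
#' @param nBoot bootstrap replicates per size (default 500).
#' @param formingP cluster-forming threshold (default 0.05, the
#'   convention of stability runs).
#' @param alpha cluster-wise significance threshold (default 0.05).
#' @param corrected TRUE counts cluster-corrected significance in the
#'   per-vertex frequency maps; FALSE counts uncorrected
#'   (vertex-level p < formingP).
#' @param metric assay name (default: first assay).
#' @param seed master seed.
#' @return a [StabilityResult-class].
#' @export
bootstrapStability <- function(ve, quartets, design, referenceClusters,
                               null, sizes = seq(15L, 50L, by = 5L),
                               nBoot = 500L, formingP = 0.05,
                               alpha = 0.05, corrected = TRUE,
                               metric = NULL, seed = 1L) {
  stopIfNot(nBoot >= 1, "at least one bootstrap replicate required")
  cq <- quartets[quartets$complete, , drop = FALSE]
  nQ <- nrow(cq)
  if (any(sizes > nQ)) {
    stop(sprintf(
      "requested size %d exceeds the %d available complete quartets",
      max(sizes), nQ), call. = FALSE)
  }
  metric <- metric %||% SummarizedExperiment::assayNames(ve)[1]
  mesh <- vxMesh(ve)
  phen <- phenotypes(ve)
  Yfull <- t(SummarizedExperiment::assay(ve, metric))
  rowOf <- setNames(seq_len(nrow(phen)), phen$subject_id)
  memberRows <- lapply(seq_len(nQ), function(i)
    unname(rowOf[c(cq$asd_f[i], cq$asd_m[i], cq$td_f[i], cq$td_m[i])]))
  refs <- referenceClusters@clusters
  nRef <- length(refs)
  detection <- matrix(0, length(sizes), max(nRef, 1))
  freqMaps <- matrix(0, nVertices(mesh), length(sizes))
  # the term F is invariant under covariate centering, so one design
  # matrix over the full cohort can be row-subset per replicate
  Xall <- buildDesign(phen, design@covariates)
  termCol <- which(colnames(Xall) == design@term)
  counter <- 0L
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    hits <- numeric(max(nRef, 1))
    vertHits <- numeric(nVertices(mesh))
    for (b in seq_len(nBoot)) {
      counter <- counter + 1L
      idx <- withSeed(replicateSeed(seed, counter),
                      sample.int(nQ, s, replace = FALSE))
      rows <- unlist(memberRows[idx], use.names = FALSE)
      fit <- termF1df(Xall[rows, , drop = FALSE],
                      Yfull[rows, , drop = FALSE], termCol)
      cl <- extractClusters(fit$p, fit$tSigned, mesh, formingP,
                            smoothness = null@smoothness)
      cl <- assignClusterwiseP(cl, null)
      sig <- Filter(function(c) c$clusterwiseP <= alpha, cl@clusters)
      for (ri in seq_len(nRef)) {
        found <- any(vapply(sig, function(c)
          c$sign == refs[[ri]]$sign &&
            diceOverlap(c$vertices, refs[[ri]]$vertices) > 0.25,
          logical(1)))
        if (found) hits[ri] <- hits[ri] + 1
      }
      if (corrected) {
        for (c in sig) vertHits[c$vertices] <- vertHits[c$vertices] + 1
      } else {
        up <- which(fit$p < formingP)
        vertHits[up] <- vertHits[up] + 1
      }
    }
    detection[si, ] <- hits / nBoot
    freqMaps[, si] <- vertHits / nBoot
  }
  colnames(detection) <- if (nRef) paste0("cluster", seq_len(nRef)) else
    "cluster1"
  new("StabilityResult", sizes = as.integer(sizes),
      nBoot = as.integer(nBoot), detection = detection,
      freqMaps = freqMaps, alpha = alpha, formingP = formingP,
      corrected = corrected, referenceClusters = referenceClusters,
      seed = as.integer(seed))
}

#' Per-vertex detection-frequency map for one sample size
#'
#' @param result a [StabilityResult-class].
#' @param size one of the per-group sizes in the result.
#' @return numeric vector: per-vertex fraction of replicates
#'   significant at the configured threshold.
#' @export
frequencyMap <- function(result, size) {
  si <- match(size, result@sizes)
  if (is.na(si))
    stop("size ", size, " not present in the stability result",
         call. = FALSE)
  result@freqMaps[, si]
}

#' Plot detection frequency against per-group sample size
#'
#' @param result a [StabilityResult-class].
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the detection matrix.
#' @export
plotStabilityCurves <- function(result, ...) {
  graphics::matplot(result@sizes, result@detection, type = "b",
                    pch = 19, lty = 1,
                    xlab = "per-group sample size",
                    ylab = "detection frequency", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  invisible(result@detection)
}
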