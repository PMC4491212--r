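# Synthetic multi-site cohort generator: phenotype tables with
# sex-scaled global volumes, quartet-linked site/age structure, and
# subject-by-vertex metric matrices with smooth noise and planted
# effect clusters of specified Cohen's f.

# Site labels and sampling weights default to the per-site totals of
# the multi-site cohort the generator emulates (11 sites, 210 subjects).
.defaultSites <- c(Caltech = 16, CMU = 12, KKI = 16, Leuven = 8,
                   Max_Mun = 12, NYU = 40, OLIN = 11, Pitt = 16,
                   UCLA = 23, UM = 24, Yale = 32)

.groupNames <- c("ASD_F", "ASD_M", "TD_F", "TD_M")

#' Describe a planted effect cluster
#'
#' @param seedVertex vertex index the region is grown from.
#' @param targetAreaCm2 target cluster area in cm^2.
#' @param metric one of "volume", "thickness", "lgi".
#' @param effectType "sex_main", "diagnosis_main" or "interaction".
#' @param cohensF Cohen's f of the planted effect (>= 0); the vertex
#'   coefficient is f * noiseSD on the +/-1 effect coding, so the
#'   balanced-design between-cell SD of means is f * noiseSD.
#' @param direction +1 or -1.  For an interaction, +1 puts the negative
#'   cell on ASD males (the lowest-in-ASD-males pattern).
#' @return a list descriptor for [cohortSpec()]'s `effectClusters`.
#' @export
effectCluster <- function(seedVertex, targetAreaCm2, metric = "lgi",
                          effectType = c("interaction", "sex_main",
                                         "diagnosis_main"),
                          cohensF = 0.253, direction = 1) {
  effectType <- match.arg(effectType)
  stopIfNot(cohensF >= 0, "cohensF must be >= 0")
  stopIfNot(targetAreaCm2 >= 0, "target area must be >= 0")
  stopIfNot(direction %in% c(-1, 1), "direction must be +1 or -1")
  list(seedVertex = as.integer(seedVertex),
       targetAreaCm2 = targetAreaCm2, metric = metric,
       effectType = effectType, cohensF = cohensF,
       direction = direction)
}

#' Construct a cohort specification
#'
#' Defaults emulate the multi-site autism case-control cohort the
#' package is modelled on: group sizes 53/53/51/53 across 11 sites
#' (weights proportional to the published per-site totals), ages from
#' a truncated normal (mean 17.1, SD 8.3, range 8-40 years),
#' supratentorial volume anchors per group (ASD F 982 +/- 120, ASD M
#' 1109 +/- 124, TD F 981 +/- 91, TD M 1098 +/- 105 cm^3) and
#' sex-independent component shares, so a supratentorial covariate
#' removes the sex effect on the components.  Vertex noise is a smooth
#' Gaussian field (default 15 mm FWHM, SD 1).
#'
#' @param groupSizes named integer vector (ASD_F, ASD_M, TD_F, TD_M).
#' @param sites,siteWeights site labels and sampling weights.
#' @param ageMean,ageSD,ageRange age distribution parameters (years).
#' @param volMeans,volSDs per-group supratentorial volume (cm^3).
#' @param volShares cortical/white/subcortical shares (sum to 1).
#' @param shareJitterSD per-subject share perturbation SD.
#' @param fsiqMeans,fsiqSDs per-group full-scale IQ parameters.
#' @param siteOffsetSD SD of the scalar per-site vertex offset
#'   (default 0.3 * noiseSD, a scanner-level shift).
#' @param noiseSD,noiseFWHM vertex noise SD and target FWHM (mm).
#' @param betaAge,betaCV covariate slopes on the vertex metrics.
#' @param effectClusters list of [effectCluster()] descriptors.
#' @param matched TRUE (default) generates quartet-linked sites and
#'   ages, mirroring a cohort constructed by matching; FALSE draws
#'   sites and ages independently per subject.
#' @param ageJitterSD within-quartet age jitter (years).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(groupSizes = c(ASD_F = 53L, ASD_M = 53L,
                                      TD_F = 51L, TD_M = 53L),
                       sites = names(.defaultSites),
                       siteWeights = unname(.defaultSites),
                       ageMean = 17.1, ageSD = 8.3, ageRange = c(8, 40),
                       volMeans = c(ASD_F = 982, ASD_M = 1109,
                                    TD_F = 981, TD_M = 1098),
                       volSDs = c(ASD_F = 120, ASD_M = 124,
                                  TD_F = 91, TD_M = 105),
                       volShares = c(cortical = 0.5078,
                                     white = 0.4312,
                                     subcortical = 0.0610),
                       shareJitterSD = 0.01,
                       fsiqMeans = c(ASD_F = 107.8, ASD_M = 102.4,
                                     TD_F = 111.2, TD_M = 107.8),
                       fsiqSDs = c(ASD_F = 17.1, ASD_M = 16.5,
                                   TD_F = 12.1, TD_M = 9.7),
                       siteOffsetSD = 0.3 * noiseSD,
                       noiseSD = 1, noiseFWHM = 15,
                       betaAge = -0.01, betaCV = 0.001,
                       effectClusters = list(),
                       matched = TRUE, ageJitterSD = 0.5) {
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  volShares <- volShares / sum(volShares)
  new("CohortSpec",
      groupSizes = gs, sites = sites, siteWeights = siteWeights,
      ageMean = ageMean, ageSD = ageSD, ageRange = ageRange,
      volMeans = volMeans, volSDs = volSDs, volShares = volShares,
      shareJitterSD = shareJitterSD,
      fsiqMeans = fsiqMeans, fsiqSDs = fsiqSDs,
      siteOffsetSD = siteOffsetSD,
      noiseSD = noiseSD, noiseFWHM = noiseFWHM,
      betaAge = betaAge, betaCV = betaCV,
      effectClusters = effectClusters,
      matched = matched, ageJitterSD = ageJitterSD)
}

drawVolumes <- function(n, group, spec) {
  supra <- rtruncnorm(n, spec@volMeans[[group]], spec@volSDs[[group]],
                      1e-6, Inf)
  shares <- matrix(rep(spec@volShares, each = n), n, 3)
  shares <- shares + matrix(rnorm(3 * n, 0, spec@shareJitterSD), n, 3)
  shares <- pmax(shares, 1e-3)
  shares <- shares / rowSums(shares)
  data.frame(supratentorial_vol = supra,
             cortical_vol = supra * shares[, 1],
             white_vol = supra * shares[, 2],
             subcortical_vol = supra * shares[, 3])
}

#' Generate a synthetic phenotype table
#'
#' Draws subjects per group with site assignment, truncated-normal
#' ages, sex-scaled supratentorial volumes and component volumes as
#' jittered sex-independent shares (so the supratentorial sum
#' invariant holds exactly).  In matched mode (the default), sites and
#' ages are generated at the quartet level: each quartet shares one
#' site and one base age with small per-member jitter, and the
#' typically developing female is omitted from the last quartets when
#' her group is smaller than the others, mirroring a cohort in which
#' some sites lacked a matching control female.  Deterministic given
#' `seed`.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed.
#' @return a data.frame with columns subject_id, site, sex, diagnosis,
#'   age, fsiq, supratentorial_vol, cortical_vol, white_vol,
#'   subcortical_vol, ados_total (ASD rows only) and, in matched mode,
#'   quartet_id.
#' @export
generatePhenotypes <- function(spec, seed = 1L) {
  validObject(spec)
  gs <- spec@groupSizes[.groupNames]
  if (sum(gs) == 0) {
    return(data.frame(subject_id = character(), site = character(),
                      sex = character(), diagnosis = character(),
                      age = numeric(), fsiq = numeric(),
                      supratentorial_vol = numeric(),
                      cortical_vol = numeric(), white_vol = numeric(),
                      subcortical_vol = numeric()))
  }
  stopIfNot(length(spec@sites) > 0,
            "site list may not be empty for a nonzero cohort")
  withSeed(seed, {
    if (spec@matched) {
      nq <- max(gs)
      qsite <- sample(spec@sites, nq, replace = TRUE,
                      prob = spec@siteWeights)
      qage <- rtruncnorm(nq, spec@ageMean, spec@ageSD,
                         spec@ageRange[1], spec@ageRange[2])
      rows <- list()
      for (g in .groupNames) {
        if (gs[[g]] == 0L) next
        take <- seq_len(gs[[g]])
        age <- qage[take] + rnorm(gs[[g]], 0, spec@ageJitterSD)
        age <- pmin(pmax(age, spec@ageRange[1]), spec@ageRange[2])
        rows[[g]] <- data.frame(
          quartet_id = take, site = qsite[take],
          group = rep(g, gs[[g]]), age = age)
      }
      tab <- do.call(rbind, rows)
    } else {
      tab <- do.call(rbind, lapply(.groupNames, function(g) {
        n <- gs[[g]]
        if (n == 0) return(NULL)
        data.frame(
          quartet_id = NA_integer_,
          site = sample(spec@sites, n, replace = TRUE,
                        prob = spec@siteWeights),
          group = g,
          age = rtruncnorm(n, spec@ageMean, spec@ageSD,
                           spec@ageRange[1], spec@ageRange[2]))
      }))
    }
    tab$diagnosis <- ifelse(grepl("^ASD", tab$group), "ASD", "TD")
    tab$sex <- ifelse(grepl("_F$", tab$group), "F", "M")
    vols <- do.call(rbind, lapply(.groupNames, function(g)
      drawVolumes(sum(tab$group == g), g, spec)))
    # drawVolumes consumed group blocks in .groupNames order; tab rows
    # are already in that order
    tab <- cbind(tab, vols)
    tab$fsiq <- unlist(lapply(.groupNames, function(g)
      rnorm(sum(tab$group == g), spec@fsiqMeans[[g]], spec@fsiqSDs[[g]])))
    tab$ados_total <- ifelse(tab$diagnosis == "ASD",
                             rnorm(nrow(tab), 11.6, 4.0), NA_real_)
    tab$subject_id <- sprintf("SUB%05d", seq_len(nrow(tab)))
    rownames(tab) <- tab$subject_id
    tab[, c("subject_id", "site", "sex", "diagnosis", "age", "fsiq",
            "supratentorial_vol", "cortical_vol", "white_vol",
            "subcortical_vol", "ados_total", "quartet_id")]
  })
}

#' Grow a contiguous vertex mask of a target area
#'
#' Breadth-first region growth from a seed vertex until the summed
#' vertex area reaches `targetAreaCm2`.  Level order, index-sorted
#' within levels, so the mask is deterministic and contiguous.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param seedVertex starting vertex index.
#' @param targetAreaCm2 target area in cm^2 (0 gives an empty mask).
#' @return integer vector of vertex indices.
#' @export
plantEffectCluster <- function(mesh, seedVertex, targetAreaCm2) {
  stopIfNot(seedVertex >= 1 && seedVertex <= nVertices(mesh),
            "seed vertex out of range")
  stopIfNot(targetAreaCm2 * 100 <= sum(mesh@vertexArea),
            "target area exceeds total mesh area")
  if (targetAreaCm2 <= 0) return(integer())
  targetMm2 <- targetAreaCm2 * 100
  va <- mesh@vertexArea
  adj <- mesh@adjacency
  inMask <- logical(nVertices(mesh))
  mask <- integer()
  frontier <- as.integer(seedVertex)
  inMask[frontier] <- TRUE
  acc <- 0
  while (acc < targetMm2 && length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      mask <- c(mask, v)
      acc <- acc + va[v]
      if (acc >= targetMm2) break
      nb <- adj[[v]]
      nb <- nb[!inMask[nb]]
      inMask[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- sort(nxt)
  }
  sort(mask)
}

effectCoding <- function(phen, effectType) {
  sex <- ifelse(phen$sex == "F", 1, -1)
  dx <- ifelse(phen$diagnosis == "ASD", 1, -1)
  switch(effectType,
         sex_main = sex,
         diagnosis_main = dx,
         interaction = sex * dx,
         stop("unknown effect type: ", effectType))
}

#' Generate subject-by-vertex metric data
#'
#' Per vertex v and subject i the value is
#' baseline + betaAge*age_i + betaCV*cortical_vol_i + siteOffset(site_i)
#' + sum over clusters of f*sigma*g_i over the cluster mask + noise,
#' where g_i is the +/-1 effect coding of the cluster's effect type
#' and the noise is a spatially smooth Gaussian field at the spec's
#' FWHM, scaled to per-vertex SD `noiseSD`.  With this coding the
#' balanced-design Cohen's f inside a mask equals the cluster's
#' `cohensF` (the between-sex difference is 2*f*sigma).
#'
#' @param phen phenotype table from [generatePhenotypes()].
#' @param mesh a [SurfaceMesh-class].
#' @param spec the [CohortSpec-class].
#' @param seed integer seed.
#' @param metrics character vector of assays to generate.
#' @return a [VertexExperiment-class] with one assay per metric and
#'   truth masks in `metadata()`.
#' @export
generateVertexMetrics <- function(phen, mesh, spec, seed = 1L,
                                  metrics = c("lgi")) {
  stopIfNot(nrow(phen) > 0, "phenotype table is empty")
  validObject(spec)
  n <- nrow(phen)
  nv <- nVertices(mesh)
  baselines <- c(volume = 0.5, thickness = 2.5, lgi = 3.0)
  masks <- list()
  for (ci in seq_along(spec@effectClusters)) {
    cl <- spec@effectClusters[[ci]]
    masks[[ci]] <- c(cl, list(
      vertices = plantEffectCluster(mesh, cl$seedVertex,
                                    cl$targetAreaCm2)))
  }
  names(masks) <- vapply(seq_along(masks), function(i)
    paste0(masks[[i]]$metric, "_", masks[[i]]$effectType, "_", i),
    character(1))
  assays <- withSeed(seed, {
    out <- list()
    for (metric in metrics) {
      siteOffset <- setNames(rnorm(length(spec@sites), 0,
                                   spec@siteOffsetSD), spec@sites)
      noise <- matrix(rnorm(nv * n), nv, n)
      if (spec@noiseFWHM >= mesh@meanEdgeLength / 2)
        noise <- smoothMap(mesh, noise, spec@noiseFWHM)
      # smoothing shrinks variance; rescale each subject's map so the
      # per-vertex SD across subjects is the configured noiseSD
      csd <- sqrt(colSums(sweep(noise, 2, colMeans(noise), "-")^2) /
                    (nv - 1))
      noise <- sweep(noise, 2, spec@noiseSD / csd, "*")
      subjEff <- rep(baselines[[metric]], n) +
        spec@betaAge * phen$age +
        spec@betaCV * phen$cortical_vol +
        siteOffset[phen$site]
      Y <- noise + matrix(subjEff, nv, n, byrow = TRUE)
      for (mk in masks) {
        if (mk$metric != metric || mk$cohensF == 0 ||
            !length(mk$vertices)) next
        g <- effectCoding(phen, mk$effectType) * mk$direction
        Y[mk$vertices, ] <- Y[mk$vertices, ] +
          outer(rep(mk$cohensF * spec@noiseSD, length(mk$vertices)), g)
      }
      dimnames(Y) <- list(NULL, phen$subject_id)
      out[[metric]] <- Y
    }
    out
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(phen, row.names = phen$subject_id),
    metadata = list(mesh = mesh, truthMasks = masks, spec = spec,
                    seed = as.integer(seed)))
  new("VertexExperiment", se)
}

# ---- external formats ------------------------------------------------

#' Write / read phenotype tables in composite-phenotype CSV convention
#'
#' Uses the multi-site consortium header convention (SUB_ID, SITE_ID,
#' DX_GROUP with 1=ASD/2=TD, SEX with 1=M/2=F, AGE_AT_SCAN, FIQ) plus
#' volume columns, so real consortium phenotype exports drop in
#' unchanged.  The internal representation normalises to
#' {ASD,TD} x {F,M}.
#'
#' @param phen internal phenotype data.frame.
#' @param path CSV path.
#' @return `readPhenotypes` returns the internal representation; the
#'   writer returns `path` invisibly.
#' @export
writePhenotypes <- function(phen, path) {
  out <- data.frame(
    SUB_ID = phen$subject_id,
    SITE_ID = phen$site,
    DX_GROUP = ifelse(phen$diagnosis == "ASD", 1L, 2L),
    SEX = ifelse(phen$sex == "M", 1L, 2L),
    AGE_AT_SCAN = phen$age,
    FIQ = phen$fsiq,
    SUPRATENTORIAL_VOL = phen$supratentorial_vol,
    CORTICAL_VOL = phen$cortical_vol,
    WHITE_VOL = phen$white_vol,
    SUBCORTICAL_VOL = phen$subcortical_vol)
  if (!is.null(phen$ados_total)) out$ADOS_TOTAL <- phen$ados_total
  if (!is.null(phen$quartet_id)) out$QUARTET_ID <- phen$quartet_id
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  phen <- data.frame(
    subject_id = as.character(raw$SUB_ID),
    site = as.character(raw$SITE_ID),
    sex = ifelse(raw$SEX == 1L, "M", "F"),
    diagnosis = ifelse(raw$DX_GROUP == 1L, "ASD", "TD"),
    age = raw$AGE_AT_SCAN,
    fsiq = if (!is.null(raw$FIQ)) raw$FIQ else NA_real_)
  for (nm in c("supratentorial_vol", "cortical_vol", "white_vol",
               "subcortical_vol")) {
    cn <- toupper(nm)
    phen[[nm]] <- if (!is.null(raw[[cn]])) raw[[cn]] else NA_real_
  }
  if (!is.null(raw$ADOS_TOTAL)) phen$ados_total <- raw$ADOS_TOTAL
  if (!is.null(raw$QUARTET_ID)) phen$quartet_id <- raw$QUARTET_ID
  rownames(phen) <- phen$subject_id
  phen
}

#' Write / read a subject-by-vertex matrix with a JSON sidecar
#'
#' The matrix is stored as little-endian doubles; the sidecar
#' (`<path>.json`) records dimensions, metric, mesh id and seed for
#' provenance.
#'
#' @param mat vertex-by-subject numeric matrix.
#' @param path output path for the binary payload.
#' @param metric,meshIdent,seed provenance fields for the sidecar.
#' @return `readVertexMatrix` returns the matrix with provenance in
#'   attributes; the writer returns `path` invisibly.
#' @export
writeVertexMatrix <- function(mat, path, metric = "map",
                              meshIdent = "", seed = NA_integer_) {
  con <- file(path, "wb")
  writeBin(as.numeric(mat), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(nrow = nrow(mat), ncol = ncol(mat), metric = metric,
         mesh_id = meshIdent, seed = seed,
         subjects = colnames(mat) %||% character()),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVertexMatrix
#' @export
readVertexMatrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n = side$nrow * side$ncol, size = 8,
                  endian = "little")
  close(con)
  mat <- matrix(vals, side$nrow, side$ncol)
  if (length(side$subjects)) colnames(mat) <- side$subjects
  attr(mat, "metric") <- side$metric
  attr(mat, "mesh_id") <- side$mesh_id
  attr(mat, "seed") <- side$seed
  mat
}
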