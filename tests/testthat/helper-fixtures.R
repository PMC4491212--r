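# Shared fixtures, built once per test run.  Mesh construction and
# smoothing calibration are cached so repeated tests stay fast.

.fixtures <- new.env(parent = emptyenv())

deskMesh <- function() {
  if (is.null(.fixtures$desk)) .fixtures$desk <- buildMesh(4)
  .fixtures$desk
}

smallMesh <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- buildMesh(3)
  .fixtures$small
}

fineMesh <- function() {
  if (is.null(.fixtures$fine)) .fixtures$fine <- buildMesh(5)
  .fixtures$fine
}

# Cohort with one planted interaction cluster at the published effect
# size (f = 0.253, ~8 cm^2) under the default study conditions.
paperLikeCohort <- function(seed = 42L) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtures[[key]])) {
    spec <- cohortSpec(effectClusters = list(
      effectCluster(101L, 8.0, "lgi", "interaction", 0.253)))
    phen <- generatePhenotypes(spec, seed)
    ve <- generateVertexMetrics(phen, deskMesh(), spec, seed + 1L,
                                metrics = "lgi")
    .fixtures[[key]] <- list(spec = spec, phen = phen, ve = ve)
  }
  .fixtures[[key]]
}

# Cohort with a stronger, larger interaction cluster (f = 0.35,
# 12 cm^2) whose full-cohort forming-0.05 analysis is significant --
# used to exercise stability properties whose premise requires a
# full-cohort-significant cluster.
strongCohort <- function(seed = 11L) {
  if (is.null(.fixtures$strong)) {
    spec <- cohortSpec(effectClusters = list(
      effectCluster(101L, 12.0, "lgi", "interaction", 0.35)))
    phen <- generatePhenotypes(spec, seed)
    ve <- generateVertexMetrics(phen, deskMesh(), spec, seed + 1L,
                                metrics = "lgi")
    .fixtures$strong <- list(spec = spec, phen = phen, ve = ve)
  }
  .fixtures$strong
}

# Stability scaffolding on the strong cohort (full-cohort significant
# at the stability thresholds, so detection properties have a
# nonvacuous premise): fitted GLM, matched null table, reference
# clusters and quartets, built once.
strongStability <- function() {
  if (is.null(.fixtures$strongStab)) {
    fx <- strongCohort()
    m <- deskMesh()
    design <- designSpec("interaction", c("age", "cortical_vol"))
    fit <- fitVertexGLM(fx$ve, design)
    sm <- estimateSmoothness(m, fit@residualMaps)
    null <- simulateNull(m, sm, 0.05, 500L, 71L)
    refs <- assignClusterwiseP(
      extractClusters(fit@p, fit@tSigned, m, 0.05, sm), null)
    refs@clusters <- Filter(function(c) c$clusterwiseP <= 0.05,
                            refs@clusters)
    q <- buildQuartets(fx$phen, 3.0)
    .fixtures$strongStab <- list(fx = fx, design = design, null = null,
                                 refs = refs, quartets = q$quartets)
  }
  .fixtures$strongStab
}

# Independent brute-force nested-RSS F via base lm() anova.
bruteForceTermF <- function(df, formulaFull, formulaReduced) {
  rssF <- sum(resid(lm(formulaFull, data = df))^2)
  rssR <- sum(resid(lm(formulaReduced, data = df))^2)
  pF <- length(coef(lm(formulaFull, data = df)))
  df2 <- nrow(df) - pF
  ((rssR - rssF) / 1) / (rssF / df2)
}
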