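# Synthetic cohort generator: phenotypes, planted clusters, vertex
# metrics, serialization.

test_that("phenotype generation honours sizes, anchors and invariants", {
  spec0 <- cohortSpec(groupSizes = c(ASD_F = 0L, ASD_M = 0L,
                                     TD_F = 0L, TD_M = 0L))
  expect_equal(nrow(generatePhenotypes(spec0, 1L)), 0L)

  spec <- cohortSpec()
  phen <- generatePhenotypes(spec, 3L)
  expect_equal(as.integer(table(paste(phen$diagnosis, phen$sex))[
    c("ASD F", "ASD M", "TD F", "TD M")]), c(53L, 53L, 51L, 53L))
  expect_true(all(phen$age >= 8 & phen$age <= 40))
  expect_true(all(phen$supratentorial_vol > 0))
  # exact component-sum invariant
  expect_equal(phen$supratentorial_vol,
               phen$cortical_vol + phen$white_vol + phen$subcortical_vol,
               tolerance = 1e-9)
  # determinism
  expect_identical(phen, generatePhenotypes(spec, 3L))
  expect_false(identical(phen$age, generatePhenotypes(spec, 4L)$age))
})

test_that("supratentorial draws match the group anchors at large n", {
  spec <- cohortSpec(groupSizes = c(ASD_F = 10000L, ASD_M = 0L,
                                    TD_F = 0L, TD_M = 0L))
  phen <- generatePhenotypes(spec, 9L)
  expect_lt(abs(mean(phen$supratentorial_vol) - 982), 3)
  expect_lt(abs(sd(phen$supratentorial_vol) - 120), 3)
})

test_that("region growth reaches the target area with exact bookkeeping", {
  m <- deskMesh()
  expect_length(plantEffectCluster(m, 10L, 0), 0L)

  mask <- plantEffectCluster(m, 10L, 7.99)
  area <- sum(vertexAreas(m)[mask]) / 100
  expect_gte(area, 7.99)
  expect_lte(area, 7.99 + max(vertexAreas(m)) / 100)
  # contiguity: one connected component under mesh adjacency
  comps <- surfmorph:::connectedComponents(mask, meshAdjacency(m))
  expect_length(comps, 1L)
  expect_error(plantEffectCluster(m, 10L, 1e6), "exceeds")
})

test_that("vertex metric generation is deterministic with finite values", {
  fx <- paperLikeCohort()
  ve2 <- generateVertexMetrics(fx$phen, deskMesh(), fx$spec, 43L,
                               metrics = "lgi")
  expect_equal(SummarizedExperiment::assay(fx$ve, "lgi"),
               SummarizedExperiment::assay(ve2, "lgi"))
  expect_true(all(is.finite(SummarizedExperiment::assay(fx$ve, "lgi"))))
  expect_equal(ncol(fx$ve), nrow(fx$phen))
})

test_that("null data give F-distributed four-group statistics", {
  m <- smallMesh()
  spec <- cohortSpec(groupSizes = c(ASD_F = 30L, ASD_M = 30L,
                                    TD_F = 30L, TD_M = 30L),
                     betaAge = 0, betaCV = 0, siteOffsetSD = 0,
                     noiseFWHM = 0)
  phen <- generatePhenotypes(spec, 21L)
  ve <- generateVertexMetrics(phen, m, spec, 22L, metrics = "lgi")
  Y <- SummarizedExperiment::assay(ve, "lgi")
  grp <- factor(paste(phen$diagnosis, phen$sex))
  Fs <- apply(Y, 1, function(y) summary(aov(y ~ grp))[[1]][1, "F value"])
  ks <- ks.test(pf(Fs, 3, 116), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effects recover their Cohen's f and leave the rest null", {
  m <- deskMesh()
  spec <- cohortSpec(
    groupSizes = c(ASD_F = 1000L, ASD_M = 1000L, TD_F = 1000L,
                   TD_M = 1000L),
    effectClusters = list(
      effectCluster(101L, 8.0, "lgi", "interaction", 0.5),
      effectCluster(1500L, 8.0, "lgi", "sex_main", 0.253)))
  phen <- generatePhenotypes(spec, 31L)
  ve <- generateVertexMetrics(phen, m, spec, 32L, metrics = "lgi")
  masks <- truthMasks(ve)
  Y <- SummarizedExperiment::assay(ve, "lgi")

  # direct group-mean / pooled-SD oracle, site removed as in the
  # matched analysis
  design <- designSpec("interaction", c("age", "cortical_vol", "site"))
  fInt <- fitVertexGLM(ve, design)
  # the sex term is validated without the sex-scaled volume covariate
  fSex <- fitVertexGLM(ve, designSpec("sex", c("age", "site")))
  fhatInt <- mean(fInt@effectF[masks[[1]]$vertices])
  fhatSex <- mean(fSex@effectF[masks[[2]]$vertices])
  expect_lt(abs(fhatInt - 0.5) / 0.5, 0.10)
  expect_lt(abs(fhatSex - 0.253) / 0.253, 0.10)

  # outside all masks the groups are exchangeable
  outside <- setdiff(seq_len(nVertices(m)),
                     unlist(lapply(masks, `[[`, "vertices")))
  g <- surfmorph:::effectCoding(phen, "interaction")
  outMeans <- colMeans(Y[outside, ])
  tt <- t.test(outMeans[g == 1], outMeans[g == -1])
  expect_gt(tt$p.value, 0.01)
})

test_that("residual maps carry the configured noise smoothness", {
  fx <- paperLikeCohort()
  fit <- fitVertexGLM(fx$ve, designSpec("interaction",
                                        c("age", "cortical_vol")))
  est <- estimateSmoothness(deskMesh(), fit@residualMaps)
  expect_lt(abs(est - fx$spec@noiseFWHM) / fx$spec@noiseFWHM, 0.20)
})

test_that("phenotype CSV round-trips through the consortium header coding", {
  fx <- paperLikeCohort()
  path <- tempfile(fileext = ".csv")
  writePhenotypes(fx$phen, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "SUB_ID,SITE_ID,DX_GROUP,SEX,AGE_AT_SCAN,FIQ")
  back <- readPhenotypes(path)
  expect_equal(back$sex, fx$phen$sex)
  expect_equal(back$diagnosis, fx$phen$diagnosis)
  expect_equal(back$supratentorial_vol, fx$phen$supratentorial_vol,
               tolerance = 1e-6)
})

test_that("vertex matrices round-trip through the binary container", {
  mat <- matrix(rnorm(60), 10, 6,
                dimnames = list(NULL, paste0("S", 1:6)))
  path <- tempfile()
  writeVertexMatrix(mat, path, metric = "lgi", meshIdent = "abc",
                    seed = 7L)
  back <- readVertexMatrix(path)
  expect_equal(unname(back[, ]), unname(mat[, ]))
  expect_equal(colnames(back), colnames(mat))
  expect_equal(attr(back, "metric"), "lgi")
  expect_equal(attr(back, "seed"), 7L)
})
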