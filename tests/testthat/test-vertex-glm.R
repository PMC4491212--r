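# Vertex-wise GLM, global ANCOVAs, post-hoc comparisons, demographics.

toyPhen <- function(n = 12, seed = 2) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("T%02d", 1:n),
    site = "X",
    sex = rep(c("F", "M"), n / 2),
    diagnosis = rep(c("ASD", "TD"), each = n / 2),
    age = seq(10, 20, length.out = n),
    fsiq = rnorm(n, 100, 10),
    cortical_vol = rnorm(n, 500, 40),
    supratentorial_vol = rnorm(n, 1000, 80))
}

toyExperiment <- function(phen, Y, mesh) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lgi = Y),
    colData = S4Vectors::DataFrame(phen, row.names = phen$subject_id),
    metadata = list(mesh = mesh, truthMasks = list()))
  new("VertexExperiment", se)
}

test_that("interaction F equals brute-force nested-RSS arithmetic", {
  phen <- toyPhen()
  m <- buildMesh(0)   # 12 vertices suffice for a toy
  set.seed(3)
  Y <- matrix(rnorm(12 * nrow(phen)), 12, nrow(phen),
              dimnames = list(NULL, phen$subject_id))
  ve <- toyExperiment(phen, Y, m)
  fit <- fitVertexGLM(ve, designSpec("interaction", "age"))

  sex <- ifelse(phen$sex == "F", 1, -1)
  dx <- ifelse(phen$diagnosis == "ASD", 1, -1)
  for (v in c(1, 5, 12)) {
    df <- data.frame(y = Y[v, ], sex = sex, dx = dx,
                     age = phen$age - mean(phen$age))
    # explicit RSS arithmetic, no shared code path
    Xf <- cbind(1, sex, dx, sex * dx, df$age)
    Xr <- Xf[, -4]
    rssF <- sum((df$y - Xf %*% solve(crossprod(Xf), crossprod(Xf, df$y)))^2)
    rssR <- sum((df$y - Xr %*% solve(crossprod(Xr), crossprod(Xr, df$y)))^2)
    Fexp <- (rssR - rssF) / (rssF / (nrow(df) - 5))
    expect_equal(fit@statF[v], Fexp, tolerance = 1e-10)
    # and against lm()'s anova as a second independent route
    Flm <- bruteForceTermF(df, y ~ sex * dx + age, y ~ sex + dx + age)
    expect_equal(fit@statF[v], Flm, tolerance = 1e-8)
  }
  expect_equal(fit@df2, nrow(phen) - 5)
  # algebraic identity of the effect-size map
  expect_equal(fit@effectF, sqrt(fit@statF * fit@df1 / fit@df2))
})

test_that("zero-noise planted effects are recovered exactly", {
  phen <- toyPhen(n = 16)
  m <- buildMesh(0)
  sex <- ifelse(phen$sex == "F", 1, -1)
  Y <- matrix(2, 12, 16)
  Y[3, ] <- 2 + 0.5 * sex          # pure sex effect at vertex 3
  ve <- toyExperiment(phen, Y, m)
  fit <- fitVertexGLM(ve, designSpec("sex", "age"))
  expect_lt(fit@p[3], 1e-12)
  expect_equal(unname(fit@coefficients["sex", 3]), 0.5,
               tolerance = 1e-10)
  expect_equal(unname(fit@coefficients["sex", 1]), 0,
               tolerance = 1e-10)
})

test_that("thickness-convention design has rank 5 and no volume covariate", {
  fx <- paperLikeCohort()
  X <- surfmorph:::buildDesign(fx$phen, "age")
  expect_equal(ncol(X), 5L)
  expect_equal(colnames(X),
               c("intercept", "sex", "diagnosis", "interaction", "age"))
  expect_equal(qr(X)$rank, 5L)
})

test_that("rank deficiency is reported with the collinear column named", {
  phen <- toyPhen()
  phen$cortical_vol <- phen$age * 2 + 5   # collinear with age
  m <- buildMesh(0)
  Y <- matrix(rnorm(12 * nrow(phen)), 12, nrow(phen))
  ve <- toyExperiment(phen, Y, m)
  expect_error(
    fitVertexGLM(ve, designSpec("sex", c("age", "cortical_vol"))),
    "cortical_vol")
})

test_that("global ANCOVAs show the sex-scaling pattern of the volume anchors", {
  spec <- cohortSpec()
  comps <- c("cortical_vol", "white_vol", "subcortical_vol")
  corrected <- c()
  for (s in 23:27) {
    phen <- generatePhenotypes(spec, s)
    for (v in c("supratentorial_vol", comps)) {
      res <- globalAncova(phen, v)
      expect_lt(res$p[res$term == "sex"], 0.001)
    }
    for (v in comps) {
      res <- globalAncova(phen, v,
                          extraCovariates = "supratentorial_vol")
      corrected <- c(corrected, res$p[res$term == "sex"])
    }
  }
  # once supratentorial scaling is accounted for, the component sex
  # effects vanish: the corrected p values behave like null draws
  expect_gt(median(corrected), 0.2)
  expect_lt(mean(corrected < 0.05), 0.2)
  phen <- generatePhenotypes(spec, 23L)
  expect_error(globalAncova(cbind(phen, const = 1), "const"),
               "constant")
})

test_that("ANCOVA p values are calibrated under exchangeable groups", {
  set.seed(33)
  ps <- replicate(200, {
    phen <- toyPhen(n = 40, seed = sample.int(1e6, 1))
    phen$y <- rnorm(40)
    globalAncova(phen, "y")$p[1]
  })
  ks <- ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster post-hoc pairwise F matches brute force on a small toy", {
  phen <- toyPhen(n = 8)
  phen$sex <- rep(c("F", "M"), 4)
  phen$diagnosis <- rep(c("ASD", "TD"), each = 4)
  m <- buildMesh(0)
  set.seed(4)
  Y <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(NULL, phen$subject_id))
  ve <- toyExperiment(phen, Y, m)
  mask <- 1:3
  res <- clusterPosthoc(ve, mask, designSpec("interaction", "age"))
  expect_equal(nrow(res), 6L)

  w <- vertexAreas(m)[mask]
  cm <- as.numeric(crossprod(Y[mask, ], w) / sum(w))
  grp <- paste(phen$diagnosis, phen$sex)
  for (k in 1:2) {
    g1 <- res$group1[k]; g2 <- res$group2[k]
    sel <- grp %in% c(g1, g2)
    df <- data.frame(y = cm[sel],
                     g = as.numeric(grp[sel] == g1),
                     age = phen$age[sel])
    Flm <- bruteForceTermF(df, y ~ g + age, y ~ age)
    expect_equal(res$F[k], Flm, tolerance = 1e-8)
  }
})

test_that("a planted lowest-in-ASD-males pattern shows in the post-hocs", {
  m <- deskMesh()
  # interaction plus sex main effect on the same mask gives the
  # ASD-male-lowest, ASD-female-highest cell pattern
  spec <- cohortSpec(
    groupSizes = c(ASD_F = 120L, ASD_M = 120L, TD_F = 120L,
                   TD_M = 120L),
    effectClusters = list(
      effectCluster(101L, 8.0, "lgi", "interaction", 0.3),
      effectCluster(101L, 8.0, "lgi", "sex_main", 0.2)))
  phen <- generatePhenotypes(spec, 51L)
  ve <- generateVertexMetrics(phen, m, spec, 52L, metrics = "lgi")
  mask <- truthMasks(ve)[[1]]$vertices
  res <- clusterPosthoc(ve, mask, designSpec("interaction",
                                             c("age", "cortical_vol")))
  asdM <- res[res$group1 == "ASD M" | res$group2 == "ASD M", ]
  expect_true(all(asdM$p < 0.05))
  # ASD M sits at the bottom of every pairwise contrast
  diffTo <- ifelse(asdM$group1 == "ASD M", asdM$difference,
                   -asdM$difference)
  expect_true(all(diffTo < 0))
  # the TD-only contrast is weaker than any ASD M contrast
  tdOnly <- res[res$group1 == "TD F" & res$group2 == "TD M", ]
  expect_lt(abs(tdOnly$difference), min(abs(asdM$difference)))
})

test_that("cohort summary reproduces textbook ANOVA and matched ages", {
  phen <- toyPhen(n = 20)
  grp <- factor(paste(phen$diagnosis, phen$sex))
  res <- cohortSummary(phen, columns = "age", caseColumns = character())
  msb <- sum(tapply(phen$age, grp, length) *
               (tapply(phen$age, grp, mean) - mean(phen$age))^2) / 3
  msw <- sum((phen$age - ave(phen$age, grp))^2) / (20 - 4)
  expect_equal(res$anova$F[1], msb / msw, tolerance = 1e-10)

  spec <- cohortSpec()
  phen2 <- generatePhenotypes(spec, 29L)
  res2 <- cohortSummary(phen2)
  expect_gt(res2$anova$p[res2$anova$variable == "age"], 0.9)
  expect_true("ados_total" %in% res2$caseOnly$variable)
  expect_warning(cohortSummary(phen2, columns = c("age", "nope")),
                 "skipped")
})

test_that("orthogonal centred covariates leave factor coefficients unchanged", {
  phen <- toyPhen(n = 24)
  m <- buildMesh(0)
  set.seed(6)
  Y <- matrix(rnorm(12 * 24), 12, 24,
              dimnames = list(NULL, phen$subject_id))
  # balanced design: make the covariate orthogonal to every factor
  # column (equal +/-20 split within each sex-by-diagnosis cell)
  phen$cortical_vol <- 500 + rep(c(-20, -20, 20, 20), 6)
  ve <- toyExperiment(phen, Y, m)
  f1 <- fitVertexGLM(ve, designSpec("interaction", character()))
  f2 <- fitVertexGLM(ve, designSpec("interaction", "cortical_vol"))
  expect_equal(f1@coefficients["interaction", ],
               f2@coefficients["interaction", ], tolerance = 1e-8)
})

test_that("vertex-wise p values are uniform under the null", {
  m <- smallMesh()
  spec <- cohortSpec(groupSizes = c(ASD_F = 40L, ASD_M = 40L,
                                    TD_F = 40L, TD_M = 40L),
                     noiseFWHM = 0, siteOffsetSD = 0)
  phen <- generatePhenotypes(spec, 61L)
  ve <- generateVertexMetrics(phen, m, spec, 62L, metrics = "lgi")
  fit <- fitVertexGLM(ve, designSpec("interaction",
                                     c("age", "cortical_vol")))
  ks <- ks.test(fit@p, "punif")
  expect_gt(ks$p.value, 0.01)
})
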