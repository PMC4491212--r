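# Vertex-wise general linear model, global-volume ANCOVAs, cluster
# post-hoc pairwise comparisons and cohort demographics summary.
#
# Factors are effect coded (+/-1: sex F=+1, diagnosis ASD=+1,
# interaction = product); covariates are mean-centred before fitting,
# and term tests use nested-model residual-sum-of-squares comparisons
# (Type-III-like in unbalanced cells).

#' Construct a design specification
#'
#' @param term factor whose extra-sum-of-squares F is reported:
#'   "sex", "diagnosis" or "interaction".
#' @param covariates ordered subset of c("age", "cortical_vol",
#'   "site", "fsiq").  Surface metric conventions: local volume and
#'   gyrification models include age and cortical volume; thickness
#'   models include age only; site and fsiq are sensitivity covariates.
#' @return a [DesignSpec-class].
#' @export
designSpec <- function(term = c("interaction", "sex", "diagnosis"),
                       covariates = c("age", "cortical_vol")) {
  term <- match.arg(term)
  new("DesignSpec", term = term, covariates = as.character(covariates))
}

# Build the design matrix.  Returns the matrix plus the column indices
# belonging to each factor term.
buildDesign <- function(phen, covariates) {
  n <- nrow(phen)
  sex <- ifelse(phen$sex == "F", 1, -1)
  dx <- ifelse(phen$diagnosis == "ASD", 1, -1)
  X <- cbind(intercept = rep(1, n), sex = sex, diagnosis = dx,
             interaction = sex * dx)
  for (cv in covariates) {
    if (cv == "site") {
      sites <- sort(unique(phen$site))
      if (length(sites) > 1) {
        for (s in sites[-1]) {
          col <- as.numeric(phen$site == s)
          X <- cbind(X, setNames(data.frame(col - mean(col)),
                                 paste0("site_", s))[[1]])
          colnames(X)[ncol(X)] <- paste0("site_", s)
        }
      }
    } else {
      v <- phen[[if (cv == "age") "age" else
                 if (cv == "cortical_vol") "cortical_vol" else "fsiq"]]
      X <- cbind(X, setNames(v - mean(v), cv))
      colnames(X)[ncol(X)] <- cv
    }
  }
  X
}

# Nested-RSS F tests of `term` columns on a response matrix Y (n x V).
# Errors on rank deficiency, naming the collinear columns.
nestedF <- function(X, Y, termCols) {
  qrf <- qr(X)
  if (qrf$rank < ncol(X)) {
    bad <- colnames(X)[qrf$pivot[(qrf$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  df1 <- length(termCols)
  df2 <- n - qrf$rank
  stopIfNot(df2 > 0, "more parameters than subjects")
  resF <- qr.resid(qrf, Y)
  rssF <- colSums(resF^2)
  qrr <- qr(X[, -termCols, drop = FALSE])
  rssR <- colSums(qr.resid(qrr, Y)^2)
  Fstat <- pmax((rssR - rssF) / df1, 0) / pmax(rssF / df2, .Machine$double.xmin)
  coefs <- qr.coef(qrf, Y)
  list(Fstat = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, coefficients = coefs, residuals = resF,
       rssFull = rssF, rssReduced = rssR)
}

# Fast 1-df term test for the bootstrap hot loop.  By the
# Frisch-Waugh theorem the term's extra sum of squares is (u'Y)^2 for
# u the unit-norm residual of the term column on the other columns;
# the full-model RSS comes from projecting Y on the reduced model's
# orthonormal basis.  Numerically equivalent to nestedF (same nested
# RSS comparison) but avoids forming residual matrices.
termF1df <- function(X, Y, termCol) {
  Xr <- X[, -termCol, drop = FALSE]
  qrr <- qr(Xr)
  u <- qr.resid(qrr, X[, termCol])
  un <- sqrt(sum(u^2))
  stopIfNot(un > 1e-8, "term column is collinear with the covariates")
  u <- u / un
  Qr <- qr.qy(qrr, diag(1, nrow(Xr), qrr$rank))
  uY <- as.numeric(crossprod(u, Y))
  rssR <- colSums(Y^2) - colSums(crossprod(Qr, Y)^2)
  rssF <- pmax(rssR - uY^2, 0)
  df2 <- nrow(X) - qrr$rank - 1L
  Fstat <- uY^2 / pmax(rssF / df2, .Machine$double.xmin)
  list(Fstat = Fstat,
       p = pmin(pmax(pf(Fstat, 1, df2, lower.tail = FALSE),
                     .Machine$double.xmin), 1),
       tSigned = sign(uY) * sqrt(Fstat), df1 = 1L, df2 = df2)
}

#' Fit the vertex-wise GLM
#'
#' Ordinary least squares at every vertex with a shared design matrix;
#' the term of interest is tested by comparing nested models on
#' residual sums of squares.  The effect-size map is the partial
#' Cohen's f, sqrt(F * df1 / df2).
#'
#' @param ve a [VertexExperiment-class].
#' @param design a [DesignSpec-class].
#' @param metric assay name to analyse (default: first assay).
#' @return a [VertexGLM-class].
#' @export
fitVertexGLM <- function(ve, design, metric = NULL) {
  validObject(design)
  metric <- metric %||% SummarizedExperiment::assayNames(ve)[1]
  phen <- phenotypes(ve)
  Y <- t(SummarizedExperiment::assay(ve, metric))   # subjects x vertices
  X <- buildDesign(phen, design@covariates)
  termCols <- which(colnames(X) == design@term)
  fit <- nestedF(X, Y, termCols)
  tSigned <- sign(fit$coefficients[termCols, ]) * sqrt(fit$Fstat)
  new("VertexGLM",
      statF = fit$Fstat,
      p = pmin(pmax(fit$p, .Machine$double.xmin), 1),
      tSigned = as.numeric(tSigned),
      effectF = sqrt(fit$Fstat * fit$df1 / fit$df2),
      coefficients = fit$coefficients,
      residualMaps = t(fit$residuals),
      df1 = fit$df1, df2 = fit$df2,
      term = design@term, metric = metric, design = design,
      nSubjects = nrow(phen))
}

#' Factorial ANCOVA on a global volume measure
#'
#' 2 x 2 analysis with sex and diagnosis as effect-coded factors,
#' their interaction, age as a covariate, and optional extra
#' covariates (e.g. `"supratentorial_vol"` to test whether component
#' volume differences survive correction for overall brain scaling).
#'
#' @param phen phenotype table.
#' @param dependent column name of the dependent volume.
#' @param extraCovariates character vector of additional phenotype
#'   columns entered mean-centred.
#' @return data.frame with F, p, df for sex, diagnosis, interaction.
#' @export
globalAncova <- function(phen, dependent,
                         extraCovariates = character()) {
  stopIfNot(dependent %in% names(phen),
            paste("dependent column not found:", dependent))
  y <- phen[[dependent]]
  stopIfNot(sd(y) > 0, "dependent variable is constant")
  X <- buildDesign(phen, "age")
  for (cv in extraCovariates) {
    v <- phen[[cv]]
    X <- cbind(X, v - mean(v))
    colnames(X)[ncol(X)] <- cv
  }
  Y <- matrix(y, ncol = 1)
  out <- lapply(c("sex", "diagnosis", "interaction"), function(tm) {
    fit <- nestedF(X, Y, which(colnames(X) == tm))
    data.frame(term = tm, F = fit$Fstat, p = fit$p,
               df1 = fit$df1, df2 = fit$df2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

starsFor <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Pairwise group ANCOVAs on a cluster mean
#'
#' Summarises each subject by the area-weighted mean of the metric
#' over the cluster mask, then runs an ANCOVA (group indicator plus
#' the design's non-site covariates, mean-centred) for each of the six
#' group pairs, with conventional star annotation (*p<0.05, **p<0.01,
#' ***p<0.001).
#'
#' @param ve a [VertexExperiment-class].
#' @param mask integer vertex indices of the cluster.
#' @param design a [DesignSpec-class] supplying the covariates.
#' @param metric assay name (default: first assay).
#' @return data.frame with group1, group2, their adjusted difference
#'   (group1 minus group2), F, p and stars.
#' @export
clusterPosthoc <- function(ve, mask, design, metric = NULL) {
  stopIfNot(length(mask) > 0, "cluster mask is empty")
  mesh <- vxMesh(ve)
  stopIfNot(all(mask >= 1 & mask <= nVertices(mesh)),
            "mask is not on the mesh")
  metric <- metric %||% SummarizedExperiment::assayNames(ve)[1]
  phen <- phenotypes(ve)
  w <- mesh@vertexArea[mask]
  vals <- as.numeric(
    crossprod(SummarizedExperiment::assay(ve, metric)[mask, ,
                                                      drop = FALSE],
              w) / sum(w))
  groups <- paste(phen$diagnosis, phen$sex, sep = " ")
  covs <- setdiff(design@covariates, "site")
  pairs <- utils::combn(sort(unique(groups)), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sel <- groups %in% c(g1, g2)
    ind <- as.numeric(groups[sel] == g1)
    X <- cbind(intercept = 1, group = ind - mean(ind))
    for (cv in covs) {
      v <- phen[[if (cv == "age") "age" else
                 if (cv == "cortical_vol") "cortical_vol" else "fsiq"]][sel]
      X <- cbind(X, v - mean(v))
      colnames(X)[ncol(X)] <- cv
    }
    fit <- nestedF(X, matrix(vals[sel], ncol = 1),
                   which(colnames(X) == "group"))
    data.frame(group1 = g1, group2 = g2,
               difference = fit$coefficients["group", 1],
               F = fit$Fstat, p = fit$p, stars = starsFor(fit$p))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Demographic and cognitive cohort summary
#'
#' One-way ANOVA F and p across the four groups for each continuous
#' demographic column (age, fsiq, and any column named in `columns`),
#' Tukey-adjusted pairwise p values, and two-group Welch t-tests
#' between ASD females and males for case-only score columns (such as
#' symptom totals).
#'
#' @param phen phenotype table.
#' @param columns columns to summarise across the four groups.
#' @param caseColumns case-only columns compared ASD F vs ASD M.
#' @return list with `anova` (data.frame), `pairwise` (list of Tukey
#'   tables) and `caseOnly` (data.frame).
#' @export
cohortSummary <- function(phen, columns = c("age", "fsiq"),
                          caseColumns = "ados_total") {
  grp <- factor(paste(phen$diagnosis, phen$sex, sep = "_"))
  stopIfNot(nlevels(grp) == 4L, "all four groups must be present")
  anovaRows <- list()
  pairwise <- list()
  for (cn in columns) {
    if (is.null(phen[[cn]])) {
      warning("column not found, skipped: ", cn)
      next
    }
    ok <- is.finite(phen[[cn]])
    fit <- aov(phen[[cn]][ok] ~ grp[ok])
    an <- summary(fit)[[1]]
    anovaRows[[cn]] <- data.frame(
      variable = cn, F = an[1, "F value"], p = an[1, "Pr(>F)"])
    tk <- TukeyHSD(fit)[[1]]
    pairwise[[cn]] <- data.frame(pair = rownames(tk),
                                 diff = tk[, "diff"],
                                 p_adj = tk[, "p adj"],
                                 row.names = NULL)
  }
  caseRows <- list()
  for (cn in caseColumns) {
    if (is.null(phen[[cn]])) next
    f <- phen[[cn]][phen$diagnosis == "ASD" & phen$sex == "F"]
    m <- phen[[cn]][phen$diagnosis == "ASD" & phen$sex == "M"]
    f <- f[is.finite(f)]; m <- m[is.finite(m)]
    if (length(f) < 2 || length(m) < 2) next
    tt <- t.test(f, m)
    caseRows[[cn]] <- data.frame(variable = cn,
                                 mean_asd_f = mean(f),
                                 mean_asd_m = mean(m),
                                 t = unname(tt$statistic),
                                 p = tt$p.value)
  }
  list(anova = do.call(rbind, c(anovaRows, list(NULL))),
       pairwise = pairwise,
       caseOnly = do.call(rbind, c(caseRows, list(NULL))))
}
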