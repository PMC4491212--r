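---
title: "Vertex-wise surface morphometry: model, cluster inference, stability and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-wise surface morphometry: model, cluster inference, stability and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(surfmorph)
```

## The problem

Studies of sex differences in autism spectrum disorder (ASD) face a
structural shortage of affected females.  The design this package
models pools structural MRI across many acquisition sites, matches
each ASD female by site and age to an ASD male, a typically
developing (TD) female and a TD male, and then asks three questions
at every vertex of the registered cortical surface: is there a main
effect of sex, of diagnosis, or a sex-by-diagnosis interaction in
cortical volume, thickness or local gyrification?  Because such
cohorts are hard to assemble, two methodological add-ons matter as
much as the group analysis itself: a bootstrap subsampling analysis
that measures how reliably a finding would have been detected in
smaller cohorts, and an effect-size-based power model that converts
an observed effect into a required sample size.

`surfmorph` implements the full pipeline — surface model, synthetic
cohort generator, quartet matching, vertex-wise GLM, Monte-Carlo
cluster-extent correction, bootstrap stability and power — as
testable units with a synthetic ground truth, so every stage can be
validated without access to restricted imaging data.

## Surface model

Statistics on the cortical surface depend on per-vertex areas, the
adjacency structure and the spatial smoothness of the maps — not on
cortical geometry.  `buildMesh()` therefore uses an area-calibrated
icosphere: a subdivided icosahedron rescaled so its total area equals
a cortical-hemisphere analog (default 1000 cm^2).  The default desk
scale is `subdivisions = 4` (2,562 vertices, mean edge ~6.7 mm);
`subdivisions = 7` gives 163,842 vertices, the resolution class of
full cortical meshes (over 150,000 vertices per hemisphere).

**Smoothing.**  Maps are smoothed by an iterated diffusion
`W = I + alpha (A - D)` with `alpha = 0.03`.  Rows and columns of `W`
sum to one, so the map mean and sum are conserved exactly, and the
small `alpha` makes each step a mild blur so that the iteration count
resolves a target FWHM to within a few percent.  Because no closed
form links iteration count to FWHM on an irregular mesh, the mapping
is calibrated empirically per mesh (`calibrateSmoothing()`): white
noise is smoothed step by step until the smoothness estimate reaches
the target; the result is cached and derived under a fixed internal
RNG substream, so it is deterministic and does not disturb user-level
seeds.

**Smoothness estimation.**  `estimateSmoothness()` uses the standard
Gaussian-random-field estimator from the variance of
neighbouring-vertex differences,

FWHM = e * sqrt(-2 ln 2 / ln(1 - Dvar / (2 var))),

with `e` the mean edge length.  Two properties are worth knowing.
First, the estimator and the calibrated smoother are self-consistent
by construction, which is what cluster inference needs (the null
fields are generated by the same operator).  Second, when the kernel
is barely resolved by the mesh (sigma below about one edge length)
the estimator carries a nugget bias, so sequential smoothing departs
from exact quadrature addition of FWHMs on coarse meshes.  The
quadrature checks in the test suite therefore run on a
`subdivisions = 5` mesh (edge ~3.4 mm), where a 10 mm kernel applied
to a 10.5 mm field reproduces the expected sqrt(10.5^2 + 10^2) =
14.5 mm within the stated tolerance.

## Synthetic cohort generator

`cohortSpec()` fixes the study conditions; its defaults are the
conditions the rest of the package is exercised under, and they are
not tuned per analysis:

* group sizes 53/53/51/53 (ASD F / ASD M / TD F / TD M) over 11
  sites with weights proportional to a realistic multi-site
  enrolment (site totals 16, 12, 16, 8, 12, 40, 11, 16, 23, 24, 32);
* age from a truncated normal, mean 17.1, SD 8.3 years, range 8–40;
* supratentorial volume anchors per group (means 982/1109/981/1098
  cm^3, SDs 120/124/91/105): males larger than females, no diagnosis
  effect;
* cortical/white/subcortical volumes as jittered, sex-independent
  shares of the supratentorial volume, so the component sum is exact
  and correcting for supratentorial volume removes component sex
  effects;
* vertex noise: per-subject Gaussian fields smoothed to 15 mm FWHM
  and rescaled to unit SD; scalar per-site offsets (SD 0.3) model
  scanner-level shifts;
* mild covariate slopes (age, cortical volume) on the vertex
  metrics.

**Planted effects.**  An `effectCluster()` grows a contiguous mask of
a target area by breadth-first search and adds `f * sigma * g_i` to
the mask vertices, where `g_i` is the +/-1 effect coding of the
cluster's term (sex F=+1, diagnosis ASD=+1, interaction their
product).  In a balanced two-by-two design the between-cell standard
deviation of means is then `f * sigma`, i.e. the planted Cohen's f
equals `f` by construction (the male–female difference is
`2 f sigma`).  Truth masks travel with the data
(`truthMasks(ve)`), so detection can always be scored against ground
truth.

Two analysis conventions follow from this construction and are used
in the validation suite.  The planted f is defined against the
vertex noise SD, so when *validating* recovery the GLM includes site
as a covariate (the scalar site offsets are a nuisance that would
otherwise inflate the residual SD by about 5%).  And the sex term is
validated without the cortical-volume covariate: cortical volume is
itself sex-scaled, so partialling it out estimates a different,
conditional effect (about 11% smaller here) — a genuine property of
ANCOVA with a sex-correlated covariate, not an implementation error.

**What the generator does not emulate.**  Real cortical geometry,
spatially varying smoothness, heteroscedastic sites, longitudinal
structure, and — importantly — spatially *graded* effects: planted
clusters are uniform boxes with sharp edges.  The last point shapes
what the stability analysis can reproduce (below).

## Quartet matching

`buildQuartets()` is greedy and deterministic: ASD females in
ascending subject-id order; for each, the unused same-site candidate
with the smallest absolute age difference (ties by id) from each
other group, subject to a caliper (default 3 years, anchored at the
ASD female's age).  A missing TD female leaves an incomplete quartet
whose other three members are retained; a missing ASD or TD male
drops the ASD female entirely.  Greedy nearest-age matching is not
globally optimal, but on enumerable toys it is within 10% of the
brute-force optimum, and it makes the construction reproducible and
order-invariant.  Only complete quartets enter the bootstrap.

The packaged availability fixture (`availabilityFixture()`, also
shipped as a synthetic CSV under `inst/extdata/`) encodes a
matching situation in which two sites each lack one control female;
quartet construction on it retains 53/53/51/53 = 210 subjects with
51 complete quartets.

## Vertex-wise GLM

`fitVertexGLM()` fits ordinary least squares at every vertex with a
shared design matrix: effect-coded factors (sex, diagnosis,
interaction) and mean-centred covariates.  Term tests compare nested
models on residual sums of squares (Type-III-like in unbalanced
cells); the effect-size map is the partial Cohen's
`f = sqrt(F * df1 / df2)`.  Metric conventions: local volume and
gyrification models include age and cortical volume; thickness
models include age only (mean thickness is not sex-scaled); site and
full-scale IQ are sensitivity covariates.  The bootstrap uses an
algebraically identical 1-df fast path (Frisch–Waugh projection)
verified against the generic route to near machine precision.

## Cluster inference

`extractClusters()` forms connected components of suprathreshold
vertices (positive and negative effects separately);
`simulateNull()` estimates the null distribution of the maximal
cluster extent by smoothing white Gaussian maps to the
residual-estimated FWHM, standardizing, thresholding and clustering;
`assignClusterwiseP()` uses the add-one estimator
`(1 + #{null >= area}) / (1 + nSims)`, which is monotone in area and
never exactly zero.  Null tables are cached and matched on mesh,
forming threshold and a 1 mm smoothness bin; the default is
residual-based smoothness per analysis.  The main analysis uses a
cluster-forming threshold of p < 0.01; stability runs use the more
permissive p < 0.05 convention.

## Bootstrap stability

`bootstrapStability()` draws complete quartets without replacement
at per-group sizes 15–50 (step 5, 500 replicates by default), reruns
the GLM and cluster inference on each subsample, and scores
detection of each reference cluster as any significant same-sign
cluster with Dice overlap above 0.25.  Reference clusters are
defined by the full-cohort *main* analysis (forming p 0.01) and then
hunted at the stability thresholds (forming p 0.05, cluster-wise
alpha 0.05), mirroring how such analyses define a finding at a
stringent threshold and ask whether it survives a conventional one
in subsamples.  Replicate seeds derive from the master seed by
counter, so any single replicate can be reproduced in isolation.  At
the full complete-quartet count every replicate is the identical
cohort, so detection is exactly 0 or 1.

**A structural limitation worth stating plainly.**  With 15 mm
smoothness over 1000 cm^2 (about 440 resels), the alpha = 0.05
critical maximal-cluster extent at forming p 0.05 is close to
9 cm^2.  A sharp, uniform 8 cm^2 planted cluster at f = 0.253
produces subsample suprathreshold extents mostly *below* that
cutoff, so its corrected detection frequency at 30 per group is far
lower than what is reported for comparable real effects.  Real
effects are spatially graded: their extent at a permissive threshold
is much larger than their core at a stringent one, which is what
makes subsample survival common in practice.  The generator's
sharp-box translation of "an 8 cm^2 cluster" therefore understates
subsample detection, and the package documents this rather than
inflating the planted effect.  Properties that require a
full-cohort-significant cluster (monotone detection in size,
detection = 1 at full size) are demonstrated on a cohort with one
stronger planted cluster (f = 0.35, 12 cm^2), chosen once from the
power arithmetic so the premise holds, and not revisited.

## Power model

The power model treats a cluster-level finding as a single 1-df
contrast with noncentrality lambda = f^2 N (Cohen's f, total N):
power(N) = Phi(f sqrt(N) - z_crit).  Instead of assuming a nominal
alpha, `calibratePowerModel()` solves z_crit from an anchor triple
(f, N, power) — e.g. "power 0.80 at N = 220 for f = 0.253".  The
three anchor triples used in the validation suite imply z_crit
between 2.91 and 2.96 (range below 0.06), i.e. they are mutually
consistent under the lambda = f^2 N convention while matching no
round alpha; the implied two-sided alpha (~0.003) is exposed rather
than hidden.  An exact noncentral-F mode solves the analogous
critical value with df1 = 1 and agrees with the normal approximation
to within 0.01 for residual df above 100.  `requiredN()` inverts the
curve to the smallest per-group n (four groups, N = 4n).

## Numerical choices and problem sizes

* Diffusion step `alpha = 0.03`; FWHM-to-iterations calibration uses
  24 white-noise maps and an internal seed derived from the target
  FWHM.
* Degenerate inputs: zero-variance maps raise an error in the
  smoothness estimator; FWHM below half the mean edge length returns
  the input with a warning (and the null simulation proceeds
  unsmoothed with a warning); empty suprathreshold sets yield empty
  cluster lists, not errors.
* The validation suite runs on the desk mesh (2,562 vertices) with
  cohorts of 53/53/51/53, 500–1000 null simulations, 100–500
  bootstrap replicates per size, and up to 1000 subjects per group
  for effect-size recovery; the smoothness quadrature checks use the
  10,242-vertex mesh.  These sizes were chosen so the full suite
  exercises every stage at meaningful precision.
* All randomness flows through explicit seeds; mesh/FWHM calibration
  caches and replicate-level seed streams keep results identical
  across runs and across machines using the same R version.

## Known limitations

Uniform vertex density (no areal distortion from registration), one
hemisphere per mesh (bilateral analyses run two meshes), scalar site
offsets rather than site-by-variance effects, no mixed-effects site
model, no random-field-theory analytic correction, and the sharp-box
planted effects discussed above.  None of these affect the
contracts the package tests: exact nested-RSS statistics, calibrated
family-wise error, planted effect-size recovery, and an internally
consistent power model.
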