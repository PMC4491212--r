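# Effect-size-based achieved power and required sample size for a
# single-df factorial contrast, under the noncentrality convention
# lambda = f^2 * N (Cohen's f, total sample N).

#' Calibrate a power model from an (effect size, N, power) anchor
#'
#' Normal approximation: power(N) = Phi(f*sqrt(N) - zCrit), so the
#' anchor fixes zCrit = f*sqrt(NAnchor) - qnorm(powerAnchor).  This
#' sidesteps guessing a nominal alpha: published (effect size,
#' required-n, power) triples pin the critical deviate directly, and
#' the implied two-sided alpha is reported.  An exact noncentral-F
#' mode solves the analogous critical value with lambda = f^2 * N and
#' df1 = 1.
#'
#' @param f Cohen's f (> 0).
#' @param NAnchor total sample size of the anchor.
#' @param powerAnchor power at the anchor, in (0, 1).
#' @param mode "normal" (default) or "exactF".
#' @param rankAdjust model rank subtracted from N for the residual df
#'   in exact mode (intercept, two factors, interaction, two
#'   covariates by default).
#' @return a [PowerModel-class].
#' @examples
#' m <- calibratePowerModel(0.347, 120, 0.80)
#' m@zCrit                      # ~2.96
#' achievedPower(m, N = 210)    # ~0.98
#' @export
calibratePowerModel <- function(f, NAnchor, powerAnchor,
                                mode = c("normal", "exactF"),
                                rankAdjust = 6) {
  mode <- match.arg(mode)
  stopIfNot(f > 0, "effect size must be positive")
  stopIfNot(powerAnchor > 0 && powerAnchor < 1,
            "anchor power must lie in (0,1)")
  zCrit <- f * sqrt(NAnchor) - qnorm(powerAnchor)
  stopIfNot(zCrit > 0,
            "infeasible anchor: implied critical value is nonpositive")
  if (mode == "exactF") {
    # solve the critical F that reproduces the anchor power exactly
    # under the noncentral F with lambda = f^2 * N
    df2a <- max(NAnchor - rankAdjust, 1)
    ncp <- f^2 * NAnchor
    Fcrit <- stats::uniroot(function(Fc)
      pf(Fc, 1, df2a, ncp = ncp, lower.tail = FALSE) - powerAnchor,
      c(1e-8, 1000))$root
    alphaImplied <- pf(Fcrit, 1, df2a, lower.tail = FALSE)
    zCrit <- qnorm(1 - alphaImplied / 2)
  } else {
    alphaImplied <- 2 * pnorm(zCrit, lower.tail = FALSE)
  }
  new("PowerModel", f = f, zCrit = zCrit, mode = mode,
      alphaImplied = alphaImplied, anchorN = NAnchor,
      anchorPower = powerAnchor, rankAdjust = rankAdjust)
}

#' Achieved power at a total sample size
#'
#' @param model a [PowerModel-class].
#' @param N total sample size (> 0).
#' @param f Cohen's f (defaults to the model's anchor effect size).
#' @return rejection probability.
#' @export
achievedPower <- function(model, N, f = model@f) {
  stopIfNot(all(N > 0), "N must be positive")
  if (model@mode == "normal") {
    return(pnorm(f * sqrt(N) - model@zCrit))
  }
  # exact noncentral-F mode: the critical F at each N comes from the
  # implied alpha; power is the noncentral tail with lambda = f^2*N
  vapply(N, function(n) {
    df2 <- max(n - model@rankAdjust, 1)
    Fcrit <- qf(1 - model@alphaImplied, 1, df2)
    pf(Fcrit, 1, df2, ncp = f^2 * n, lower.tail = FALSE)
  }, numeric(1))
}

#' Smallest per-group n reaching a target power
#'
#' Four groups are assumed, so the total sample is 4n.
#'
#' @param model a [PowerModel-class].
#' @param targetPower required power, in (0, 1).
#' @param f Cohen's f (> 0; defaults to the model's).
#' @param maxN search cap on the per-group n.
#' @return integer per-group sample size.
#' @export
requiredN <- function(model, targetPower = 0.8, f = model@f,
                      maxN = 100000L) {
  stopIfNot(targetPower > 0 && targetPower < 1,
            "target power must lie in (0,1)")
  if (f <= 0)
    stop("power target unreachable for a null effect size",
         call. = FALSE)
  for (n in seq_len(maxN)) {
    if (achievedPower(model, 4 * n, f = f) >= targetPower)
      return(n)
  }
  stop("no per-group n up to ", maxN, " reaches the target power",
       call. = FALSE)
}

#' Plot achieved power against per-group sample size
#'
#' @param model a [PowerModel-class].
#' @param nRange per-group sample sizes to plot.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a data.frame of (n, power).
#' @export
plotPowerCurve <- function(model, nRange = 10:60, ...) {
  pw <- achievedPower(model, 4 * nRange)
  graphics::plot(nRange, pw, type = "l", lwd = 2,
                 xlab = "per-group sample size",
                 ylab = "achieved power", ylim = c(0, 1), ...)
  graphics::abline(h = 0.8, lty = 3, col = "grey50")
  invisible(data.frame(n = nRange, power = pw))
}
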