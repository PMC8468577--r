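# Release kinetics: Higuchi (Q ~ sqrt(t)) and Korsmeyer-Peppas
# (log10 Q ~ log10 t) fits on the 20-60 % release window, the < 4 point
# exclusion rule, mechanism classification from the release exponent, and
# pooled-variance t-tests for equality of two regression lines.

#' Restrict a profile to a release window
#'
#' Keeps the points with `lo <= released <= hi` (closed interval), in
#' original order. The kinetic fits operate on the 20-60% window by
#' convention; a profile with fewer than 4 points there is excluded from
#' kinetic analysis rather than fitted.
#'
#' @param profile a [DissolutionProfile-class].
#' @param lo,hi window bounds in percent released.
#' @return A [DissolutionProfile-class] restricted to the window (may be
#'   empty in `length`; see [fitHiguchi()] for the exclusion rule).
#' @examples
#' p <- DissolutionProfile(1:5 * 10, c(10, 25, 40, 55, 70))
#' profileReleased(releaseWindow(p))  # 25 40 55
#' @export
releaseWindow <- function(profile, lo = 20, hi = 60) {
  stopifnot(is(profile, "DissolutionProfile"))
  keep <- profile@released >= lo & profile@released <= hi
  if (!any(keep))
    return(structure(list(times = numeric(0), released = numeric(0),
                          label = profile@label),
                     class = "emptyWindow"))
  DissolutionProfile(profile@times[keep], profile@released[keep],
                     label = profile@label)
}

.windowLength <- function(w) {
  if (inherits(w, "emptyWindow")) 0L else length(w@times)
}

#' Kinetic exclusion marker
#'
#' Returned (not thrown) by the kinetic fits when fewer than 4 data points
#' fall in the release window: an exclusion is a legitimate analysis
#' outcome, distinct from a failure.
#'
#' @param x object to test.
#' @return `isExcluded` returns `TRUE` for an exclusion marker.
#' @export
isExcluded <- function(x) inherits(x, "kineticExclusion")

.exclusion <- function(model, n, lo, hi) {
  structure(list(model = model, nPoints = n,
                 reason = sprintf(
                   "only %d data points in the %g-%g%% release window",
                   n, lo, hi)),
            class = "kineticExclusion")
}

.olsFit <- function(model, x, y) {
  if (length(unique(x)) < 2L)
    stop("degenerate regressor: no variance in transformed time")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  n <- length(x)
  new("KineticFit", model = model, slope = unname(co[2L]),
      intercept = unname(co[1L]), r2 = r2,
      adjR2 = 1 - (1 - r2) * (n - 1) / (n - 2), nPoints = as.integer(n),
      rss = rss, x = x, y = y)
}

#' Fit the Higuchi model on the release window
#'
#' Ordinary least squares of released percent against the square root of
#' time in minutes, on the 20-60% window: `Q = k sqrt(t) + c`. A window
#' with fewer than 4 points yields an exclusion marker ([isExcluded()]),
#' not an error.
#'
#' @param profile a [DissolutionProfile-class] (times in minutes, release
#'   in percent).
#' @param lo,hi release window bounds in percent.
#' @return A [KineticFit-class], or a kinetic exclusion.
#' @examples
#' t <- seq(30, 300, 30)
#' fitHiguchi(DissolutionProfile(t, 2.5 * sqrt(t)))
#' @export
fitHiguchi <- function(profile, lo = 20, hi = 60) {
  w <- releaseWindow(profile, lo, hi)
  n <- .windowLength(w)
  if (n < 4L) return(.exclusion("higuchi", n, lo, hi))
  .olsFit("higuchi", sqrt(w@times), w@released)
}

#' Fit the Korsmeyer-Peppas model on the release window
#'
#' Ordinary least squares of log10(released percent) against log10(time in
#' minutes) on the 20-60% window: the slope is the release exponent n, the
#' intercept log10(k). All window points must have positive time and
#' release. Fewer than 4 window points yield an exclusion marker.
#'
#' @inheritParams fitHiguchi
#' @return A [KineticFit-class] (slope = n, intercept = log10 k), or a
#'   kinetic exclusion.
#' @examples
#' t <- seq(10, 700, 10)
#' fitKorsmeyerPeppas(DissolutionProfile(t, 5 * t^0.45))
#' @export
fitKorsmeyerPeppas <- function(profile, lo = 20, hi = 60) {
  w <- releaseWindow(profile, lo, hi)
  n <- .windowLength(w)
  if (n < 4L) return(.exclusion("korsmeyer_peppas", n, lo, hi))
  if (any(w@times <= 0) || any(w@released <= 0))
    stop("Korsmeyer-Peppas requires positive times and release values ",
         "in the window")
  .olsFit("korsmeyer_peppas", log10(w@times), log10(w@released))
}

#' Classify the release mechanism from the Korsmeyer-Peppas exponent
#'
#' For cylindrical geometry: n near or below 0.45 indicates Fickian
#' diffusion, n between 0.45 and 0.89 anomalous transport, n near or above
#' 0.89 case-II (relaxation/erosion-controlled, zero-order-like)
#' transport. The tolerance widens the Fickian and case-II bands so that
#' textbook boundary values classify as their regime.
#'
#' @param n release exponent (Korsmeyer-Peppas slope).
#' @param tol classification tolerance (default 0.02).
#' @return One of `"fickian"`, `"anomalous"`, `"case_ii"`.
#' @examples
#' classifyMechanism(0.45)  # fickian
#' classifyMechanism(0.75)  # anomalous
#' classifyMechanism(1.0)   # case_ii
#' @export
classifyMechanism <- function(n, tol = 0.02) {
  stopifnot(is.finite(n))
  if (n <= 0.45 + tol) "fickian"
  else if (n < 0.89 - tol) "anomalous"
  else "case_ii"
}

#' Adjusted R-squared of a simple linear regression fit
#'
#' `1 - (1 - R^2)(n - 1)/(n - 2)` for one regressor.
#'
#' @param fit a [KineticFit-class].
#' @return Adjusted R-squared.
#' @export
adjustedR2 <- function(fit) {
  stopifnot(is(fit, "KineticFit"))
  n <- fit@nPoints
  if (n < 3L) stop("adjusted R^2 requires at least 3 points")
  1 - (1 - fit@r2) * (n - 1) / (n - 2)
}

.regSums <- function(fit) {
  x <- fit@x; y <- fit@y; n <- length(x)
  list(n = n, mx = mean(x), my = mean(y),
       sxx = sum((x - mean(x))^2),
       sxy = sum((x - mean(x)) * (y - mean(y))),
       syy = sum((y - mean(y))^2),
       b = fit@slope, rss = fit@rss)
}

#' Test two regression lines for equal slope and elevation
#'
#' Pooled-variance t-test for equality of slopes
#' (`df = n1 + n2 - 4`); if and only if the slopes are *not* significantly
#' different at `alpha`, an elevation (intercept) test under the
#' common-slope model follows (`df = n1 + n2 - 3`). When the slope test
#' rejects, the intercept fields are `NA` — testing elevations of
#' non-parallel lines is not meaningful, which is why reports print "NA"
#' there.
#'
#' @param fitTest,fitRef [KineticFit-class] objects of the same model for
#'   the predicted and the reference (experimental) profile.
#' @param alpha significance level gating the elevation test.
#' @return A [RegressionComparison-class].
#' @examples
#' t <- seq(30, 300, 30)
#' f1 <- fitHiguchi(DissolutionProfile(t, 2.5 * sqrt(t) +
#'                                     rnorm(length(t), 0, 0.2)))
#' compareRegressions(f1, f1)
#' @export
compareRegressions <- function(fitTest, fitRef, alpha = 0.05) {
  stopifnot(is(fitTest, "KineticFit"), is(fitRef, "KineticFit"))
  if (fitTest@model != fitRef@model)
    warning("comparing fits of different kinetic models")
  a <- .regSums(fitTest); b <- .regSums(fitRef)
  if (a$sxx <= 0 || b$sxx <= 0)
    stop("degenerate regressor variance in one of the fits")
  dfS <- a$n + b$n - 4L
  sp2 <- (a$rss + b$rss) / dfS
  se <- sqrt(sp2 * (1 / a$sxx + 1 / b$sxx))
  tS <- if (se == 0) 0 else (a$b - b$b) / se
  pS <- 2 * stats::pt(-abs(tS), dfS)
  tI <- NA_real_; pI <- NA_real_; dfI <- NA_integer_
  if (!is.na(pS) && pS >= alpha) {
    bc <- (a$sxy + b$sxy) / (a$sxx + b$sxx)
    rssC <- max(0, (a$syy + b$syy) - (a$sxy + b$sxy)^2 /
                  (a$sxx + b$sxx))
    dfI <- a$n + b$n - 3L
    sc2 <- rssC / dfI
    seI <- sqrt(sc2 * (1 / a$n + 1 / b$n +
                         (a$mx - b$mx)^2 / (a$sxx + b$sxx)))
    tI <- if (seI == 0) 0
          else ((a$my - b$my) - bc * (a$mx - b$mx)) / seI
    pI <- 2 * stats::pt(-abs(tI), dfI)
  }
  new("RegressionComparison", tSlope = tS, pSlope = pS,
      tIntercept = tI, pIntercept = pI,
      dfSlope = as.integer(dfS), dfIntercept = dfI, alpha = alpha)
}

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit [%s]: slope %.4f, intercept %.4f, adj R^2 %.4f (n = %d)\n",
    object@model, object@slope, object@intercept, object@adjR2,
    object@nPoints))
  invisible(object)
})

setMethod("show", "RegressionComparison", function(object) {
  cat(sprintf("RegressionComparison: t_slope = %.3f, p_slope = %.3g\n",
              object@tSlope, object@pSlope))
  if (is.na(object@pIntercept))
    cat("  intercept test: NA (slopes significantly different)\n")
  else
    cat(sprintf("  t_intercept = %.3f, p_intercept = %.3g\n",
                object@tIntercept, object@pIntercept))
  invisible(object)
})
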