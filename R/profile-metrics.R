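# Pairwise dissolution-profile similarity: point selection on a common
# time grid, the f1 difference factor, the f2 similarity factor, and the
# conventional similarity verdict (f1 < 15 and f2 > 50).

#' Select paired profile points for similarity analysis
#'
#' Both profiles must share the time grid over the comparison window (no
#' interpolation: experiments and simulations are sampled on the same
#' grid, so a mismatch is a user error). Points are taken at all common
#' times up to `tMax` (default 720 min, the 12 h horizon) or up to the
#' complete release of the reference, whichever is earlier. Complete
#' release is the first time the reference reaches `releaseCut` (default
#' 99.5%), that point included. The t = 0 point is excluded by default (it
#' carries no information and inflates n).
#'
#' @param ref,test [DissolutionProfile-class] objects (reference =
#'   experimental, test = predicted).
#' @param tMax comparison horizon in minutes.
#' @param releaseCut percent release counted as complete.
#' @param includeZero keep a t = 0 point in the sums?
#' @return A data.frame with columns `time`, `ref`, `test` and attribute
#'   `truncationTime`.
#' @examples
#' r <- DissolutionProfile(seq(10, 60, 10), c(10, 20, 30, 40, 50, 60))
#' t <- DissolutionProfile(seq(10, 60, 10), c(12, 21, 33, 41, 52, 61))
#' selectPoints(r, t)
#' @export
selectPoints <- function(ref, test, tMax = 720, releaseCut = 99.5,
                         includeZero = FALSE) {
  stopifnot(is(ref, "DissolutionProfile"), is(test, "DissolutionProfile"))
  hit <- which(ref@released >= releaseCut)
  tCut <- if (length(hit)) min(tMax, ref@times[hit[1L]]) else tMax
  keepR <- ref@times <= tCut
  keepT <- test@times <= tCut
  if (!includeZero) {
    keepR <- keepR & ref@times > 0
    keepT <- keepT & test@times > 0
  }
  tr <- ref@times[keepR]
  tt <- test@times[keepT]
  if (!length(tr) || !length(tt))
    stop("no common time points within the comparison window")
  if (length(tr) != length(tt) || any(tr != tt)) {
    bad <- if (length(tr) != length(tt)) {
      setdiff(union(tr, tt), intersect(tr, tt))[1L]
    } else tr[which(tr != tt)[1L]]
    stop(sprintf(
      "time grids differ within the window (first offending time: %g ",
      bad), "min); profiles must share a common grid")
  }
  out <- data.frame(time = tr, ref = ref@released[keepR],
                    test = test@released[keepT])
  attr(out, "truncationTime") <- tCut
  out
}

.pairsRefTest <- function(pairs, test) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("ref", "test") %in% names(pairs)))
    list(ref = pairs$ref, test = pairs$test)
  } else {
    stopifnot(!is.null(test), length(pairs) == length(test))
    list(ref = as.numeric(pairs), test = as.numeric(test))
  }
}

#' f1 difference factor
#'
#' \deqn{f_1 = \frac{\sum_t |R_t - T_t|}{\sum_t R_t} \times 100}
#' 0 for identical profiles; conventional similarity requires f1 < 15.
#'
#' @param pairs data.frame from [selectPoints()] (columns `ref`, `test`),
#'   or a numeric vector of reference values with `test` supplied.
#' @param test numeric vector of test values when `pairs` is a vector.
#' @return The f1 value (nonnegative).
#' @examples
#' f1Factor(c(10, 20, 30), c(12, 22, 32))
#' @export
f1Factor <- function(pairs, test = NULL) {
  p <- .pairsRefTest(pairs, test)
  if (length(p$ref) < 1L) stop("at least one pair is required")
  sr <- sum(p$ref)
  if (sr <= 0) stop("sum of reference release values is zero")
  100 * sum(abs(p$ref - p$test)) / sr
}

#' f2 similarity factor
#'
#' \deqn{f_2 = 50 \log_{10}\!\left(\frac{100}
#'   {\sqrt{1 + \frac{1}{n}\sum_t (R_t - T_t)^2}}\right)}
#' 100 for identical profiles, about 50 at an average 10-point difference;
#' conventional similarity requires f2 > 50.
#'
#' @inheritParams f1Factor
#' @return The f2 value (at most 100).
#' @examples
#' f2Factor(c(10, 20, 30), c(20, 30, 40))  # ~ 50
#' @export
f2Factor <- function(pairs, test = NULL) {
  p <- .pairsRefTest(pairs, test)
  n <- length(p$ref)
  if (n < 1L) stop("at least one pair is required")
  50 * log10(100 / sqrt(1 + sum((p$ref - p$test)^2) / n))
}

#' Similarity verdict from f1 and f2
#'
#' `TRUE` iff `f1 < limitF1` and `f2 > limitF2` (strict inequalities, the
#' originally proposed limits being 15 and 50).
#'
#' @param f1,f2 the two factors.
#' @param limitF1,limitF2 configurable limits.
#' @return Logical verdict.
#' @examples
#' similarityVerdict(14.9, 50.1)  # TRUE
#' similarityVerdict(15.0, 100)   # FALSE
#' @export
similarityVerdict <- function(f1, f2, limitF1 = 15, limitF2 = 50) {
  (f1 < limitF1) && (f2 > limitF2)
}

#' Compare two dissolution profiles by f1/f2
#'
#' Convenience wrapper: [selectPoints()] then [f1Factor()], [f2Factor()]
#' and [similarityVerdict()].
#'
#' @inheritParams selectPoints
#' @param limitF1,limitF2 verdict limits.
#' @return A [SimilarityResult-class].
#' @examples
#' r <- DissolutionProfile(seq(10, 120, 10), seq(8, 96, 8))
#' compareProfiles(r, r)
#' @export
compareProfiles <- function(ref, test, tMax = 720, releaseCut = 99.5,
                            includeZero = FALSE, limitF1 = 15,
                            limitF2 = 50) {
  pairs <- selectPoints(ref, test, tMax = tMax, releaseCut = releaseCut,
                        includeZero = includeZero)
  f1 <- f1Factor(pairs)
  f2 <- f2Factor(pairs)
  new("SimilarityResult", f1 = f1, f2 = f2, nPoints = nrow(pairs),
      truncationTime = attr(pairs, "truncationTime"),
      verdict = similarityVerdict(f1, f2, limitF1, limitF2))
}

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf(
    "SimilarityResult: f1 = %.1f, f2 = %.1f (n = %d, up to %g min) -> %s\n",
    object@f1, object@f2, object@nPoints, object@truncationTime,
    if (object@verdict) "similar" else "not similar"))
  invisible(object)
})
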