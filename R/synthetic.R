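# Synthetic fixtures with known ground truth: analytic release profiles
# (power law / square root / logistic, optionally noisy) and voxel
# tablets whose reconstructed masses reproduce a tabulated virtual/real
# mass record, so recovery arithmetic is testable end-to-end.

#' Generate a synthetic dissolution profile
#'
#' Released fraction follows the chosen model, capped at `cap`, with
#' optional Gaussian noise (in percentage points), clipped to `[0, cap]`
#' and made non-decreasing by a running maximum (a cumulative release
#' cannot fall). Deterministic given `seed`.
#'
#' Models: `power_law` is `k * t^n`; `square_root` is `k * sqrt(t)` (the
#' Higuchi shape, i.e. power law with n = 1/2); `logistic` is
#' `cap / (1 + exp(-k (t - n)))` with `n` acting as the midpoint time.
#'
#' @param model `"power_law"`, `"square_root"` or `"logistic"`.
#' @param k rate coefficient (percent per minute^n).
#' @param n exponent (power law), ignored for `square_root`, midpoint
#'   minute for `logistic`.
#' @param times sampling grid in minutes, strictly increasing (the
#'   conventional grid samples every 10 minutes for 12 h).
#' @param noiseSd Gaussian noise standard deviation in percentage points.
#' @param cap plateau cap in percent.
#' @param seed RNG seed.
#' @param label profile label.
#' @return A [DissolutionProfile-class].
#' @examples
#' synthProfile("power_law", k = 5, n = 0.45)
#' @export
synthProfile <- function(model = c("power_law", "square_root",
                                   "logistic"),
                         k, n = 0.5, times = seq(10, 720, by = 10),
                         noiseSd = 0, cap = 100, seed = 1L,
                         label = NULL) {
  model <- match.arg(model)
  stopifnot(k > 0, noiseSd >= 0, all(diff(times) > 0))
  clean <- switch(model,
    power_law = k * times^n,
    square_root = k * sqrt(times),
    logistic = cap / (1 + exp(-k * (times - n))))
  clean <- pmin(cap, clean)
  rel <- if (noiseSd > 0) {
    .withSeed(seed, clean + stats::rnorm(length(times), 0, noiseSd))
  } else clean
  rel <- cummax(pmin(cap, pmax(0, rel)))
  if (is.null(label))
    label <- sprintf("synthetic %s (k=%g, n=%g)", model, k, n)
  DissolutionProfile(times, rel, label = label)
}

#' Build a voxel tablet reproducing a virtual/real mass record
#'
#' Generates a distributed virtual tablet whose reconstructed compound
#' masses match the record's *virtual* masses to within one voxel-mass,
#' paired with a [TabletSpec-class] built from the record's *real*
#' masses, so that [recoveryReport()] reproduces the record's recovery
#' arithmetic exactly at the printed one-decimal rounding.
#'
#' The default grid (voxel edge 0.15 mm, 24 x 80 x 80) holds a standard
#' 11.28 mm x 3.5 mm tablet at test-friendly size; it is a scale model,
#' not a 7 um-resolved image.
#'
#' @param virtualApi,virtualEx reconstructed (virtual) masses in mg.
#' @param realApi,realEx gravimetric (real) masses in mg.
#' @param api,ex [Compound-class] objects (defaults:
#'   [defaultCompounds()]).
#' @param diameter,height tablet geometry in mm.
#' @param voxelEdge voxel edge in mm.
#' @param dim grid dimensions.
#' @param seed RNG seed.
#' @return List with elements `matrix` ([VoxelMatrix-class]), `spec`
#'   ([TabletSpec-class]) and `record` (the inputs).
#' @examples
#' fx <- synthTabletFixture(virtualApi = 73.3, virtualEx = 329.2,
#'                          realApi = 86.9, realEx = 329.5)
#' recoveryRates(recoveryReport(fx$matrix, defaultCompounds()[1:2],
#'                              fx$spec, region = "cylinder"))
#' @export
synthTabletFixture <- function(virtualApi, virtualEx, realApi, realEx,
                               api = defaultCompounds()$api,
                               ex = defaultCompounds()$ex,
                               diameter = 11.28, height = 3.5,
                               voxelEdge = 0.15, dim = c(24L, 80L, 80L),
                               seed = 1L) {
  stopifnot(virtualApi > 0, virtualEx > 0, realApi > 0, realEx > 0)
  targets <- c(virtualApi, virtualEx)
  names(targets) <- c(api@name, ex@name)
  params <- GenerationParams(dim, voxelEdge, diameter, height,
                             targets = targets, mode = "distributed",
                             seed = seed)
  matrix <- generateDistributed(params, list(api, ex))
  spec <- TabletSpec(diameter, height, apiMass = realApi,
                     exMass = realEx)
  list(matrix = matrix, spec = spec,
       record = list(virtualApi = virtualApi, virtualEx = virtualEx,
                     realApi = realApi, realEx = realEx, seed = seed))
}

#' Bundled worked-example tablet table (25/75 theophylline batch)
#'
#' The selected-image table of the 25% theophylline / 75% ethyl cellulose
#' batch: per matrix, the processing pathway, tablet desirability and the
#' reconstructed API/excipient masses, with `real` rows holding the
#' gravimetric masses of the imaged tablets. Used by the worked examples
#' and the acceptance pipeline for recovery arithmetic.
#'
#' @return A data.frame with columns `name`, `tablet`, `pathway`,
#'   `desirability`, `api_mg`, `excipient_mg`.
#' @examples
#' head(exampleTabletTable())
#' @export
exampleTabletTable <- function() {
  utils::read.csv(system.file("extdata",
                              "theophylline_ec_25_75_tablets.csv",
                              package = "voxdiss"),
                  stringsAsFactors = FALSE)
}
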