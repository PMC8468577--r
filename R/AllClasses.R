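#' @import methods
NULL

#' Compound: physical and transport properties of one labelled phase
#'
#' A `Compound` carries the per-phase parameters a voxel dissolution engine
#' consumes, keyed by the 8-bit grey value that identifies the phase in a
#' labelled image stack. Solubility and density drive mass accounting and
#' dissolution; contact angle gates wettability (a phase with contact angle
#' of 90 degrees or more cannot be wetted by the medium); intraparticular
#' porosity and pore size describe sub-voxel void structure.
#'
#' @slot id integer grey value in `[0, 255]` identifying the phase.
#' @slot name character, human-readable phase name.
#' @slot density numeric, true (helium) density in kg/m^3.
#' @slot solubility numeric, solubility in the dissolution medium in mg/mL
#'   (0 for an insoluble matrix former).
#' @slot molarMass numeric, molar mass in Da (`NA` if not needed).
#' @slot contactAngle numeric, contact angle against the medium in degrees
#'   (`NA` if not needed).
#' @slot intraPorosity numeric, intraparticular porosity in percent.
#' @slot poreSize numeric, characteristic pore size in micrometres.
#'
#' @seealso [Compound()], [defaultCompounds()]
#' @exportClass Compound
setClass("Compound",
  representation(
    id = "integer",
    name = "character",
    density = "numeric",
    solubility = "numeric",
    molarMass = "numeric",
    contactAngle = "numeric",
    intraPorosity = "numeric",
    poreSize = "numeric"
  ),
  prototype(
    molarMass = NA_real_, contactAngle = NA_real_,
    intraPorosity = 0, poreSize = NA_real_
  )
)

setValidity("Compound", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id) ||
      object@id < 0L || object@id > 255L)
    msg <- c(msg, "'id' must be a single integer in [0, 255]")
  if (length(object@density) != 1L || is.na(object@density) ||
      object@density <= 0)
    msg <- c(msg, "'density' must be a single positive number (kg/m^3)")
  if (length(object@solubility) != 1L || is.na(object@solubility) ||
      object@solubility < 0)
    msg <- c(msg, "'solubility' must be >= 0 (mg/mL)")
  if (!is.na(object@contactAngle) &&
      (object@contactAngle < 0 || object@contactAngle > 180))
    msg <- c(msg, "'contactAngle' must lie in [0, 180] degrees")
  if (!is.na(object@intraPorosity) &&
      (object@intraPorosity < 0 || object@intraPorosity >= 100))
    msg <- c(msg, "'intraPorosity' must lie in [0, 100) percent")
  if (length(msg)) msg else TRUE
})

#' VoxelMatrix: a labelled 3D voxel volume representing a tablet
#'
#' The central container: a 3D grid of small-integer labels (grey values)
#' together with the physical voxel edge length and a label map declaring
#' the role of every grey value present (`"air"`, `"compound"`, or
#' `"medium"`). Axis 0 of the grid is the slice axis (image stack order);
#' within a slice, indices are (row, col) image coordinates.
#'
#' @slot labels integer 3D array, indexed `[slice, row, col]`.
#' @slot voxelEdge numeric, edge length of a voxel in mm.
#' @slot labelMap named character vector: names are grey values (as
#'   character), values are roles `"air"`, `"compound"`, or `"medium"`.
#' @slot metadata list of free-form provenance (generation parameters,
#'   cylinder geometry, RNG seed).
#'
#' @seealso [VoxelMatrix()], [readTiffStack()], [generateDistributed()]
#' @exportClass VoxelMatrix
setClass("VoxelMatrix",
  representation(
    labels = "array",
    voxelEdge = "numeric",
    labelMap = "character",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("VoxelMatrix", function(object) {
  msg <- character(0)
  d <- dim(object@labels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "'labels' must be a 3D array with all dimensions >= 1")
  if (length(object@voxelEdge) != 1L || is.na(object@voxelEdge) ||
      object@voxelEdge <= 0)
    msg <- c(msg, "'voxelEdge' must be a single positive length (mm)")
  if (is.null(names(object@labelMap)) ||
      !all(object@labelMap %in% c("air", "compound", "medium")))
    msg <- c(msg,
      "'labelMap' must be named with roles 'air', 'compound' or 'medium'")
  vals <- unique(as.vector(object@labels))
  known <- suppressWarnings(as.integer(names(object@labelMap)))
  unknown <- setdiff(vals, known)
  if (length(unknown))
    msg <- c(msg, sprintf("grey value(s) %s absent from labelMap",
                          paste(unknown, collapse = ", ")))
  if (any(vals < 0L | vals > 255L))
    msg <- c(msg, "labels must lie in the 8-bit range [0, 255]")
  if (length(msg)) msg else TRUE
})

#' TabletSpec: geometry and gravimetric composition of a real tablet
#'
#' Records the measured dimensions and per-compound masses of a physical
#' tablet; the reference against which a virtual matrix's reconstructed
#' composition is judged (recovery rates) and the input to the tablet
#' porosity calculation.
#'
#' @slot diameter numeric, tablet diameter D in mm.
#' @slot height numeric, tablet height h in mm.
#' @slot totalMass numeric, total tablet mass in mg.
#' @slot apiMass numeric, API mass in mg.
#' @slot exMass numeric, excipient (matrix former) mass in mg.
#'
#' @seealso [TabletSpec()], [tabletPorosity()], [recoveryReport()]
#' @exportClass TabletSpec
setClass("TabletSpec",
  representation(
    diameter = "numeric", height = "numeric",
    totalMass = "numeric", apiMass = "numeric", exMass = "numeric"
  )
)

setValidity("TabletSpec", function(object) {
  msg <- character(0)
  vals <- c(object@diameter, object@height, object@totalMass,
            object@apiMass, object@exMass)
  if (length(vals) != 5L || any(is.na(vals)) || any(vals <= 0))
    msg <- c(msg, "all fields must be single positive numbers")
  else if (object@apiMass + object@exMass > object@totalMass * 1.01)
    msg <- c(msg,
      "apiMass + exMass exceeds totalMass by more than 1% (binary tablet)")
  if (length(msg)) msg else TRUE
})

#' DissolutionProfile: cumulative drug release over time
#'
#' A time series of cumulative percent API released, the unit both
#' experimental dissolution testing and voxel simulators report.
#'
#' @slot times numeric, strictly increasing sampling times in minutes.
#' @slot released numeric, cumulative percent of total API released.
#' @slot label character, profile identifier.
#'
#' @seealso [DissolutionProfile()], [readProfile()], [synthProfile()]
#' @exportClass DissolutionProfile
setClass("DissolutionProfile",
  representation(times = "numeric", released = "numeric",
                 label = "character"),
  prototype(label = "profile")
)

setValidity("DissolutionProfile", function(object) {
  msg <- character(0)
  if (length(object@times) < 1L)
    msg <- c(msg, "profile must contain at least one point")
  if (length(object@times) != length(object@released))
    msg <- c(msg, "'times' and 'released' must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(object@released < 0))
    msg <- c(msg, "'released' values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CompositionReport: composition accounting of a virtual matrix
#'
#' Per-compound voxel counts and masses of a voxel matrix, its image
#' porosity, and recovery rates against a real tablet: recovered mass as a
#' percentage of the gravimetric mass, for API, excipient, total, and the
#' three pairwise mass ratios, aggregated into a Derringer-style
#' desirability in `[0, 1]`.
#'
#' @slot voxelCounts named numeric, voxels per compound name.
#' @slot masses named numeric, reconstructed mass (mg) per compound name.
#' @slot imagePorosity numeric, air fraction of the evaluated region (%).
#' @slot recovery named numeric with elements `api`, `ex`, `total`,
#'   `ratio_api_ex`, `ratio_api_total`, `ratio_ex_total` (percent).
#' @slot desirability numeric in `[0, 1]`.
#'
#' @seealso [recoveryReport()], [desirabilityScore()], [recoveryRates()]
#' @exportClass CompositionReport
setClass("CompositionReport",
  representation(
    voxelCounts = "numeric", masses = "numeric",
    imagePorosity = "numeric", recovery = "numeric",
    desirability = "numeric"
  )
)

setValidity("CompositionReport", function(object) {
  msg <- character(0)
  if (any(object@masses < 0)) msg <- c(msg, "masses must be >= 0")
  if (any(object@recovery < 0)) msg <- c(msg, "recoveries must be >= 0")
  if (length(object@desirability) == 1L && !is.na(object@desirability) &&
      (object@desirability < 0 || object@desirability > 1))
    msg <- c(msg, "desirability must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GenerationParams: recipe for a generated virtual tablet
#'
#' Parameters of the two in-software tablet construction modes: random
#' voxel placement (`"distributed"`) and seeded cluster growth
#' (`"seed_grow"`). Target masses are per compound name; the cylinder must
#' fit inside the grid.
#'
#' @slot dim integer vector (slices, rows, cols) of the voxel grid.
#' @slot voxelEdge numeric, voxel edge length in mm.
#' @slot diameter numeric, cylinder diameter in mm.
#' @slot height numeric, cylinder height in mm.
#' @slot targets named numeric, target mass (mg) per compound name.
#' @slot mode character, `"distributed"` or `"seed_grow"`.
#' @slot nSeeds integer, seeds per compound (seed_grow only).
#' @slot seed integer RNG seed.
#'
#' @seealso [GenerationParams()], [generateDistributed()],
#'   [generateSeedGrow()]
#' @exportClass GenerationParams
setClass("GenerationParams",
  representation(
    dim = "integer", voxelEdge = "numeric",
    diameter = "numeric", height = "numeric",
    targets = "numeric", mode = "character",
    nSeeds = "integer", seed = "integer"
  ),
  prototype(mode = "distributed", nSeeds = 1L, seed = 1L)
)

setValidity("GenerationParams", function(object) {
  msg <- character(0)
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "'dim' must be three positive integers")
  if (object@voxelEdge <= 0) msg <- c(msg, "'voxelEdge' must be > 0")
  if (any(object@targets < 0) || is.null(names(object@targets)))
    msg <- c(msg, "'targets' must be a named nonnegative vector (mg)")
  if (!object@mode %in% c("distributed", "seed_grow"))
    msg <- c(msg, "'mode' must be 'distributed' or 'seed_grow'")
  if (object@mode == "seed_grow" && any(object@nSeeds < 1L))
    msg <- c(msg, "'nSeeds' must be >= 1 in seed_grow mode")
  if (object@diameter > object@dim[2L] * object@voxelEdge ||
      object@diameter > object@dim[3L] * object@voxelEdge ||
      object@height > object@dim[1L] * object@voxelEdge)
    msg <- c(msg, "cylinder does not fit inside the grid")
  if (length(msg)) msg else TRUE
})

#' KineticFit: a linearised release-kinetics fit
#'
#' Ordinary least squares fit of a dissolution profile on a linearising
#' transform: released percent against sqrt(time) for the Higuchi model,
#' log10(released) against log10(time) for the Korsmeyer-Peppas model. The
#' transformed regression data are retained so fits can be compared by
#' t-tests afterwards.
#'
#' @slot model character, `"higuchi"` or `"korsmeyer_peppas"`.
#' @slot slope,intercept numeric OLS coefficients; for Korsmeyer-Peppas the
#'   slope is the release exponent n and the intercept is log10(k).
#' @slot r2,adjR2 numeric, coefficient of determination and its adjusted
#'   form for simple regression.
#' @slot nPoints integer, number of fitted window points.
#' @slot rss numeric, residual sum of squares.
#' @slot x,y numeric, transformed regressor and response actually fitted.
#'
#' @seealso [fitHiguchi()], [fitKorsmeyerPeppas()], [compareRegressions()]
#' @exportClass KineticFit
setClass("KineticFit",
  representation(
    model = "character", slope = "numeric", intercept = "numeric",
    r2 = "numeric", adjR2 = "numeric", nPoints = "integer",
    rss = "numeric", x = "numeric", y = "numeric"
  )
)

setValidity("KineticFit", function(object) {
  msg <- character(0)
  if (object@nPoints < 4L)
    msg <- c(msg, "a kinetic fit requires at least 4 window points")
  if (!is.na(object@adjR2) && object@adjR2 > 1 + 1e-12)
    msg <- c(msg, "adjusted R^2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' RegressionComparison: equality tests between two kinetic fits
#'
#' Pooled-variance t-test for equality of slopes; if and only if the slopes
#' are not significantly different at `alpha`, an elevation (intercept)
#' test under the common-slope model. When the slope test rejects, the
#' intercept fields are `NA` ("not calculated").
#'
#' @slot tSlope,pSlope numeric, slope test statistic and two-sided p.
#' @slot tIntercept,pIntercept numeric, elevation test (or `NA`).
#' @slot dfSlope,dfIntercept integer degrees of freedom.
#' @slot alpha numeric significance level gating the intercept test.
#'
#' @seealso [compareRegressions()]
#' @exportClass RegressionComparison
setClass("RegressionComparison",
  representation(
    tSlope = "numeric", pSlope = "numeric",
    tIntercept = "numeric", pIntercept = "numeric",
    dfSlope = "integer", dfIntercept = "integer", alpha = "numeric"
  )
)

setValidity("RegressionComparison", function(object) {
  ok <- function(p) is.na(p) || (p >= 0 && p <= 1)
  if (!ok(object@pSlope) || !ok(object@pIntercept))
    "p-values must lie in [0, 1]" else TRUE
})

#' SimilarityResult: f1/f2 comparison of two dissolution profiles
#'
#' @slot f1 numeric, difference factor (>= 0; 0 for identical profiles).
#' @slot f2 numeric, similarity factor (<= 100; 100 for identical
#'   profiles).
#' @slot nPoints integer, paired points entering the sums.
#' @slot truncationTime numeric, last time point used (minutes).
#' @slot verdict logical, similarity verdict at the configured limits.
#'
#' @seealso [compareProfiles()], [similarityVerdict()]
#' @exportClass SimilarityResult
setClass("SimilarityResult",
  representation(
    f1 = "numeric", f2 = "numeric", nPoints = "integer",
    truncationTime = "numeric", verdict = "logical"
  )
)

setValidity("SimilarityResult", function(object) {
  msg <- character(0)
  if (object@f1 < 0) msg <- c(msg, "f1 must be >= 0")
  if (object@f2 > 100 + 1e-9) msg <- c(msg, "f2 cannot exceed 100")
  if (object@nPoints < 1L) msg <- c(msg, "at least one point required")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the reference dissolution fixture
#'
#' Configuration of the package's small, transparent cellular-automaton
#' dissolution simulator (a reference fixture standing in for proprietary
#' engines; it reproduces no commercial tool). Field names mirror the
#' conventional simulation parameter sheet: iteration count, sampling
#' interval in seconds, a dimensionless mixing parameter for paddle
#' convection, medium properties, and per-compound records.
#'
#' @slot compounds list of [Compound-class] objects covering every
#'   non-air label of the matrix (the medium label may be included).
#' @slot iterations integer, number of time steps.
#' @slot timeStep numeric, seconds per iteration.
#' @slot samplingInterval numeric, seconds between profile samples.
#' @slot mixingParameter numeric in `[0, 1]`, convection scaling.
#' @slot rateConstant numeric, intrinsic dissolution rate coefficient in
#'   mL per exposed voxel face per second (effective clearance volume).
#' @slot wettingTime numeric, seconds for the medium to permeate a
#'   wettable excipient voxel of 100% intraparticular porosity; scaled
#'   inversely with the actual porosity.
#' @slot mediumDensity,mediumViscosity,mediumTension numeric medium
#'   properties (kg/m^3, Pa s, mN/m); passthroughs recorded in reports.
#' @slot seed integer RNG seed recorded with every run (the update rule
#'   itself is deterministic).
#'
#' @seealso [SimulationConfig()], [simulateDissolution()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    compounds = "list", iterations = "integer", timeStep = "numeric",
    samplingInterval = "numeric", mixingParameter = "numeric",
    rateConstant = "numeric", wettingTime = "numeric",
    mediumDensity = "numeric", mediumViscosity = "numeric",
    mediumTension = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@iterations < 1L) msg <- c(msg, "'iterations' must be >= 1")
  if (object@samplingInterval < 1)
    msg <- c(msg, "'samplingInterval' must be >= 1 second")
  if (object@mixingParameter < 0 || object@mixingParameter > 1)
    msg <- c(msg, "'mixingParameter' must lie in [0, 1]")
  if (object@timeStep <= 0) msg <- c(msg, "'timeStep' must be > 0")
  if (!all(vapply(object@compounds, is, logical(1), "Compound")))
    msg <- c(msg, "'compounds' must be a list of Compound objects")
  if (length(msg)) msg else TRUE
})
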