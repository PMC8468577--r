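# Composition accounting: voxel counts -> masses -> recovery rates ->
# desirability. Unit convention: voxel edge in mm, density in kg/m^3;
# 1 kg/m^3 == 1e-3 mg/mm^3, so mass_mg = n * edge^3 * density * 1e-3.

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' recovery rates), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(84.35, 1)  # 84.4, where round() would give 84.3
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  # pre-round at 8 decimals so binary representation noise (84.35 * 10 =
  # 843.4999...) cannot flip a decimal tie
  sign(x) * floor(round(abs(x) * p, 8) + 0.5) / p
}

#' Reconstructed compound masses of a voxel matrix
#'
#' Mass per compound as voxel count times voxel volume times true density,
#' i.e. every labelled voxel is treated as fully dense compound (sub-voxel
#' porosity is handled separately, by [excipientVirtualPorosity()]).
#'
#' @param matrix a [VoxelMatrix-class].
#' @param compounds list of [Compound-class] objects; every grey value with
#'   role `"compound"` that occurs in the matrix must have one.
#' @return Named numeric vector of masses in mg (names are compound names).
#' @examples
#' cmp <- defaultCompounds()
#' m <- VoxelMatrix(array(c(1L, 31L), c(2, 2, 2)), 0.028)
#' compoundMasses(m, cmp[c("api", "ex")])
#' @export
compoundMasses <- function(matrix, compounds) {
  stopifnot(is(matrix, "VoxelMatrix"))
  counts <- voxelCounts(matrix)
  roles <- matrix@labelMap[names(counts)]
  ids <- vapply(compounds, function(cp) cp@id, integer(1))
  need <- as.integer(names(counts)[roles == "compound"])
  missing <- setdiff(need, ids)
  if (length(missing))
    stop("no Compound supplied for grey value(s) ",
         paste(missing, collapse = ", "))
  vol <- matrix@voxelEdge^3                    # mm^3
  masses <- vapply(compounds, function(cp) {
    n <- counts[as.character(cp@id)]
    if (is.na(n)) n <- 0L
    as.numeric(n) * vol * cp@density * 1e-3    # mg
  }, numeric(1))
  names(masses) <- vapply(compounds, function(cp) cp@name, character(1))
  masses
}

.cylinderMask <- function(dims, voxelEdge, diameter, height) {
  # logical array: voxel centre inside the analytic cylinder, centred in
  # the grid; slice axis is the cylinder axis
  s <- (seq_len(dims[1L]) - 0.5) * voxelEdge
  r <- (seq_len(dims[2L]) - 0.5) * voxelEdge
  cc <- (seq_len(dims[3L]) - 0.5) * voxelEdge
  cz <- dims[1L] * voxelEdge / 2
  cy <- dims[2L] * voxelEdge / 2
  cx <- dims[3L] * voxelEdge / 2
  inAx <- abs(s - cz) <= height / 2
  rad2 <- outer((r - cy)^2, (cc - cx)^2, `+`)
  inRad <- rad2 <= (diameter / 2)^2
  outer(inAx, inRad, `&`)
}

#' Cylindrical evaluation mask for a voxel grid
#'
#' A voxel belongs to the cylinder if its centre lies within the analytic
#' cylinder (axis along the slice direction, centred in the grid).
#'
#' @param matrix a [VoxelMatrix-class].
#' @param diameter,height cylinder dimensions in mm; default to the
#'   generation geometry stored in the matrix metadata.
#' @return Logical array of `dim(matrix)`.
#' @examples
#' m <- VoxelMatrix(array(0L, c(4, 8, 8)), 0.5)
#' sum(cylinderMask(m, diameter = 3, height = 2))
#' @export
cylinderMask <- function(matrix, diameter = NULL, height = NULL) {
  stopifnot(is(matrix, "VoxelMatrix"))
  md <- matrix@metadata
  if (is.null(diameter)) diameter <- md$diameter
  if (is.null(height)) height <- md$height
  if (is.null(diameter) || is.null(height))
    stop("no cylinder geometry: supply 'diameter' and 'height' or use a ",
         "generated matrix carrying them in metadata")
  .cylinderMask(dim(matrix@labels), matrix@voxelEdge, diameter, height)
}

#' Image porosity of a voxel matrix
#'
#' Percentage of air voxels within the evaluation region. Uploaded
#' matrices are cropped to the tablet, so the default region is the full
#' stack; for generated tablets embedded in an air bounding box, the
#' cylindrical region (`region = "cylinder"`) restricts the count to the
#' tablet volume.
#'
#' @param matrix a [VoxelMatrix-class].
#' @param region `"all"` (default) or `"cylinder"`.
#' @param diameter,height cylinder geometry (mm) when
#'   `region = "cylinder"`; default to the matrix metadata.
#' @return Porosity in percent.
#' @examples
#' imagePorosity(VoxelMatrix(array(0L, c(2, 2, 2)), 0.028))  # 100
#' @export
imagePorosity <- function(matrix, region = c("all", "cylinder"),
                          diameter = NULL, height = NULL) {
  stopifnot(is(matrix, "VoxelMatrix"))
  region <- match.arg(region)
  airIds <- as.integer(names(matrix@labelMap)[matrix@labelMap == "air"])
  lab <- matrix@labels
  if (region == "cylinder") {
    mask <- cylinderMask(matrix, diameter, height)
    lab <- lab[mask]
  }
  if (length(lab) == 0L) stop("empty evaluation region")
  100 * sum(lab %in% airIds) / length(lab)
}

#' Linear ramp desirability for a recovery rate
#'
#' Default per-parameter desirability: a symmetric linear ramp centred on
#' 100% recovery, reaching 0 at `width` percentage points away.
#'
#' @param recovery recovery rate in percent.
#' @param width half-width of the ramp in percentage points.
#' @return Desirability in `[0, 1]`.
#' @examples
#' rampDesirability(100); rampDesirability(87.5)
#' @export
rampDesirability <- function(recovery, width = 25) {
  pmin(1, pmax(0, 1 - abs(recovery - 100) / width))
}

#' Geometric-mean desirability of six recovery parameters
#'
#' The tablet desirability is the geometric mean of the six per-parameter
#' desirabilities (API, excipient and total mass recovery plus the three
#' ratio recoveries); one zero component annihilates the score. The
#' per-parameter mapping is pluggable; the packaged default is
#' [rampDesirability()].
#'
#' @param report a [CompositionReport-class], or a numeric vector of six
#'   recovery rates in percent.
#' @param mapping function recovery (percent) -> desirability in `[0, 1]`.
#' @return Desirability in `[0, 1]`.
#' @examples
#' desirabilityScore(rep(100, 6))            # 1
#' desirabilityScore(c(100, 100, 100, 100, 100, 87.5))
#' @export
desirabilityScore <- function(report, mapping = rampDesirability) {
  rec <- if (is(report, "CompositionReport")) report@recovery
         else as.numeric(report)
  if (length(rec) != 6L)
    stop("six recovery parameters are required")
  d <- pmin(1, pmax(0, mapping(rec)))
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

#' Composition recovery report of a virtual matrix against a real tablet
#'
#' Recovery rate of a quantity is 100 times its reconstructed (virtual)
#' value over its gravimetric (real) value: computed for API mass,
#' excipient mass, total mass, and the three pairwise mass ratios, then
#' aggregated into a desirability.
#'
#' @param matrix a [VoxelMatrix-class].
#' @param compounds list of [Compound-class]; `api` and `ex` select the
#'   two phases (default: first and second element).
#' @param real a [TabletSpec-class] with the real tablet's masses.
#' @param api,ex the API and excipient [Compound-class] objects.
#' @param mapping per-parameter desirability function.
#' @param region,diameter,height forwarded to [imagePorosity()].
#' @return A [CompositionReport-class].
#' @seealso [recoveryRates()], [desirabilityScore()]
#' @examples
#' cmp <- defaultCompounds()
#' m <- VoxelMatrix(array(c(1L, 31L, 0L, 31L), c(2, 2, 2)), 0.1)
#' spec <- TabletSpec(0.3, 0.2, apiMass = compoundMasses(m, cmp[1:2])[1],
#'                    exMass = compoundMasses(m, cmp[1:2])[2])
#' recoveryRates(recoveryReport(m, cmp[1:2], spec))
#' @export
recoveryReport <- function(matrix, compounds, real,
                           api = compounds[[1L]], ex = compounds[[2L]],
                           mapping = rampDesirability,
                           region = "all", diameter = NULL,
                           height = NULL) {
  stopifnot(is(matrix, "VoxelMatrix"), is(real, "TabletSpec"))
  if (real@apiMass <= 0 || real@exMass <= 0 || real@totalMass <= 0)
    stop("real tablet masses must be positive")
  masses <- compoundMasses(matrix, list(api, ex))
  vApi <- masses[[api@name]]
  vEx <- masses[[ex@name]]
  vTot <- vApi + vEx
  rTot <- real@apiMass + real@exMass
  recovery <- c(
    api = 100 * vApi / real@apiMass,
    ex = 100 * vEx / real@exMass,
    total = 100 * vTot / rTot,
    ratio_api_ex = 100 * (vApi / vEx) / (real@apiMass / real@exMass),
    ratio_api_total = 100 * (vApi / vTot) / (real@apiMass / rTot),
    ratio_ex_total = 100 * (vEx / vTot) / (real@exMass / rTot)
  )
  counts <- voxelCounts(matrix)
  nApi <- counts[as.character(api@id)]; if (is.na(nApi)) nApi <- 0L
  nEx <- counts[as.character(ex@id)]; if (is.na(nEx)) nEx <- 0L
  vc <- as.numeric(c(nApi, nEx))
  names(vc) <- c(api@name, ex@name)
  new("CompositionReport",
      voxelCounts = vc, masses = masses,
      imagePorosity = imagePorosity(matrix, region = region,
                                    diameter = diameter, height = height),
      recovery = recovery,
      desirability = desirabilityScore(recovery, mapping))
}

#' Recovery rates of a composition report
#'
#' @param report a [CompositionReport-class].
#' @param digits decimal places for half-up rounding (the printed
#'   convention is one decimal); `NULL` returns unrounded values.
#' @return Named numeric vector of recovery rates in percent.
#' @export
recoveryRates <- function(report, digits = 1) {
  stopifnot(is(report, "CompositionReport"))
  if (is.null(digits)) report@recovery
  else roundHalfUp(report@recovery, digits)
}

#' @rdname CompositionReport-class
#' @param x,object a `CompositionReport`.
#' @param row.names,optional,... conventional arguments; unused.
#' @export
setMethod("as.data.frame", "CompositionReport",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
      parameter = c(paste0("mass_", names(x@masses)),
                    "image_porosity",
                    paste0("recovery_", names(x@recovery)),
                    "desirability"),
      value = c(unname(x@masses), x@imagePorosity,
                unname(x@recovery), x@desirability)
    )
  })

setMethod("show", "CompositionReport", function(object) {
  cat("CompositionReport\n")
  cat(sprintf("  masses (mg): %s\n",
              paste(sprintf("%s %.1f", names(object@masses),
                            object@masses), collapse = ", ")))
  cat(sprintf("  image porosity: %.1f %%\n", object@imagePorosity))
  rec <- roundHalfUp(object@recovery, 1)
  cat(sprintf("  recoveries (%%): %s\n",
              paste(sprintf("%s %.1f", names(rec), rec),
                    collapse = ", ")))
  cat(sprintf("  desirability: %.3f\n", object@desirability))
  invisible(object)
})
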