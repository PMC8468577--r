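#' Construct a VoxelMatrix
#'
#' @param labels integer 3D array indexed `[slice, row, col]`; values are
#'   8-bit grey values.
#' @param voxelEdge voxel edge length in mm (e.g. 0.028 for a 28 um grid).
#' @param labelMap named character vector mapping grey value to role
#'   (`"air"`, `"compound"`, `"medium"`); defaults to [defaultLabelMap()].
#' @param metadata list of free-form provenance.
#' @return A [VoxelMatrix-class] object.
#' @examples
#' m <- VoxelMatrix(array(0L, c(2, 4, 4)), voxelEdge = 0.028)
#' dim(m)
#' @export
VoxelMatrix <- function(labels, voxelEdge,
                        labelMap = defaultLabelMap(),
                        metadata = list()) {
  storage.mode(labels) <- "integer"
  new("VoxelMatrix", labels = labels, voxelEdge = as.numeric(voxelEdge),
      labelMap = labelMap, metadata = metadata)
}

#' @describeIn VoxelMatrix-class the label array.
#' @param x,object a `VoxelMatrix`.
#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))

#' @rdname VoxelMatrix-class
#' @export
setMethod("voxelLabels", "VoxelMatrix", function(x) x@labels)

#' @describeIn VoxelMatrix-class voxel edge length (mm).
#' @export
setGeneric("voxelEdge", function(x) standardGeneric("voxelEdge"))

#' @rdname VoxelMatrix-class
#' @export
setMethod("voxelEdge", "VoxelMatrix", function(x) x@voxelEdge)

#' @describeIn VoxelMatrix-class grey-value role map.
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname VoxelMatrix-class
#' @export
setMethod("labelMap", "VoxelMatrix", function(x) x@labelMap)

#' @describeIn VoxelMatrix-class generation/provenance metadata.
#' @export
setGeneric("voxelMetadata", function(x) standardGeneric("voxelMetadata"))

#' @rdname VoxelMatrix-class
#' @export
setMethod("voxelMetadata", "VoxelMatrix", function(x) x@metadata)

#' @rdname VoxelMatrix-class
#' @export
setMethod("dim", "VoxelMatrix", function(x) dim(x@labels))

#' Per-grey-value voxel counts
#'
#' @param x a [VoxelMatrix-class].
#' @return Named integer vector of voxel counts, names are grey values.
#' @examples
#' voxelCounts(VoxelMatrix(array(c(0L, 1L), c(2, 2, 2)), 0.028))
#' @export
voxelCounts <- function(x) {
  stopifnot(is(x, "VoxelMatrix"))
  tab <- table(x@labels)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

setMethod("show", "VoxelMatrix", function(object) {
  d <- dim(object@labels)
  cat(sprintf("VoxelMatrix: %d slices x %d rows x %d cols, edge %.4g mm\n",
              d[1L], d[2L], d[3L], object@voxelEdge))
  counts <- voxelCounts(object)
  roles <- object@labelMap[names(counts)]
  for (i in seq_along(counts))
    cat(sprintf("  grey %3s (%-8s): %d voxels\n",
                names(counts)[i], roles[i], counts[i]))
  if (!is.null(object@metadata$mode))
    cat(sprintf("  generated: mode '%s', seed %s\n",
                object@metadata$mode,
                as.character(object@metadata$seed)))
  invisible(object)
})

#' Construct a TabletSpec
#'
#' @param diameter tablet diameter in mm.
#' @param height tablet height in mm.
#' @param apiMass API mass in mg.
#' @param exMass excipient mass in mg.
#' @param totalMass total tablet mass in mg; defaults to the sum of the
#'   component masses (lubricant-free binary tablet).
#' @return A [TabletSpec-class] object.
#' @examples
#' TabletSpec(11.28, 3.5, apiMass = 86.9, exMass = 329.5)
#' @export
TabletSpec <- function(diameter, height, apiMass, exMass,
                       totalMass = apiMass + exMass) {
  new("TabletSpec", diameter = as.numeric(diameter),
      height = as.numeric(height), totalMass = as.numeric(totalMass),
      apiMass = as.numeric(apiMass), exMass = as.numeric(exMass))
}

setMethod("show", "TabletSpec", function(object) {
  cat(sprintf(
    "TabletSpec: D %.2f mm, h %.2f mm, %.1f mg (API %.1f / ex %.1f)\n",
    object@diameter, object@height, object@totalMass,
    object@apiMass, object@exMass))
  invisible(object)
})

#' Construct a DissolutionProfile
#'
#' @param times sampling times in minutes, strictly increasing.
#' @param released cumulative percent API released at each time.
#' @param label profile identifier.
#' @return A [DissolutionProfile-class] object.
#' @examples
#' DissolutionProfile(c(10, 20, 30), c(5, 9, 13), "example")
#' @export
DissolutionProfile <- function(times, released, label = "profile") {
  new("DissolutionProfile", times = as.numeric(times),
      released = as.numeric(released), label = as.character(label))
}

#' @describeIn DissolutionProfile-class sampling times (minutes).
#' @param x,object a `DissolutionProfile`.
#' @export
setGeneric("profileTimes", function(x) standardGeneric("profileTimes"))

#' @rdname DissolutionProfile-class
#' @export
setMethod("profileTimes", "DissolutionProfile", function(x) x@times)

#' @describeIn DissolutionProfile-class cumulative percent released.
#' @export
setGeneric("profileReleased", function(x) standardGeneric("profileReleased"))

#' @rdname DissolutionProfile-class
#' @export
setMethod("profileReleased", "DissolutionProfile", function(x) x@released)

#' @rdname DissolutionProfile-class
#' @export
setMethod("length", "DissolutionProfile", function(x) length(x@times))

#' @rdname DissolutionProfile-class
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "DissolutionProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(time_min = x@times, released_pct = x@released)
  })

setMethod("show", "DissolutionProfile", function(object) {
  cat(sprintf(
    "DissolutionProfile '%s': %d points, %.0f-%.0f min, final %.1f %%\n",
    object@label, length(object@times), min(object@times),
    max(object@times), object@released[length(object@released)]))
  invisible(object)
})

#' Read / write a dissolution profile CSV
#'
#' Profiles travel as two-column CSV with header `time_min,released_pct`.
#'
#' @param path file path.
#' @param label profile label; defaults to the file name.
#' @return `readProfile` returns a [DissolutionProfile-class];
#'   `writeProfile` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeProfile(DissolutionProfile(c(10, 20), c(4, 7)), f)
#' readProfile(f)
#' @export
readProfile <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "released_pct") %in% names(df)))
    stop("profile CSV must have columns 'time_min' and 'released_pct'")
  DissolutionProfile(df$time_min, df$released_pct, label = label)
}

#' @rdname readProfile
#' @param profile a [DissolutionProfile-class].
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "DissolutionProfile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
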