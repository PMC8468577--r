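#' Construct a Compound
#'
#' @param id integer grey value in `[0, 255]` identifying the phase in a
#'   labelled image stack.
#' @param name phase name.
#' @param density true density in kg/m^3.
#' @param solubility solubility in the medium in mg/mL (default 0,
#'   insoluble).
#' @param molarMass molar mass in Da.
#' @param contactAngle contact angle in degrees.
#' @param intraPorosity intraparticular porosity in percent (default 0).
#' @param poreSize characteristic pore size in micrometres.
#' @return A [Compound-class] object.
#' @examples
#' Compound(1L, "theophylline", density = 1447.2, solubility = 10.09)
#' @export
Compound <- function(id, name, density, solubility = 0,
                     molarMass = NA_real_, contactAngle = NA_real_,
                     intraPorosity = 0, poreSize = NA_real_) {
  new("Compound", id = as.integer(id), name = as.character(name),
      density = as.numeric(density), solubility = as.numeric(solubility),
      molarMass = as.numeric(molarMass),
      contactAngle = as.numeric(contactAngle),
      intraPorosity = as.numeric(intraPorosity),
      poreSize = as.numeric(poreSize))
}

#' Default compound set: theophylline / ethyl cellulose / buffer
#'
#' The standard parameter sheet of the theophylline anhydrate (API, grey
#' value 1) and ethyl cellulose (matrix former, grey value 31) model
#' system dissolving in pH 6.6 phosphate buffer (medium, grey value 200):
#' helium densities, API solubility, molar masses, the excipient contact
#' angle (89 degrees, i.e. just wettable), and its estimated pore size.
#' The excipient intraparticular porosity defaults to 0 and is normally
#' overwritten with the value of [excipientVirtualPorosity()].
#'
#' @return Named list of [Compound-class] objects
#'   (`api`, `ex`, `medium`).
#' @examples
#' defaultCompounds()$api
#' @export
defaultCompounds <- function() {
  list(
    api = Compound(1L, "theophylline", density = 1447.2,
                   solubility = 10.09, molarMass = 180.16),
    ex = Compound(31L, "ethyl cellulose", density = 1139.9,
                  solubility = 0, molarMass = 75000,
                  contactAngle = 89, intraPorosity = 0, poreSize = 0.5),
    medium = Compound(200L, "phosphate buffer", density = 1007.0)
  )
}

#' Default grey-value label map
#'
#' The conventional identification numbers: air 0, API 1, excipient 31,
#' dissolution medium 200. Fully overridable wherever a `labelMap` is
#' accepted.
#'
#' @param api,ex integer grey values of the API and excipient phases.
#' @param air,medium integer grey values of air and medium.
#' @return Named character vector mapping grey value to role.
#' @examples
#' defaultLabelMap()
#' @export
defaultLabelMap <- function(api = 1L, ex = 31L, air = 0L, medium = 200L) {
  lm <- c("air", "compound", "compound", "medium")
  names(lm) <- as.character(c(air, api, ex, medium))
  lm
}

#' @describeIn Compound-class accessor for the grey-value identifier.
#' @param object,x a `Compound`.
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))

#' @rdname Compound-class
#' @export
setMethod("compoundId", "Compound", function(x) x@id)

#' @describeIn Compound-class accessor for the compound name.
#' @export
setGeneric("compoundName", function(x) standardGeneric("compoundName"))

#' @rdname Compound-class
#' @export
setMethod("compoundName", "Compound", function(x) x@name)

setMethod("show", "Compound", function(object) {
  cat(sprintf("Compound '%s' (grey value %d)\n", object@name, object@id))
  cat(sprintf("  density %.1f kg/m^3, solubility %.4g mg/mL\n",
              object@density, object@solubility))
  if (!is.na(object@contactAngle))
    cat(sprintf("  contact angle %.1f deg (%s)\n", object@contactAngle,
                if (object@contactAngle < 90) "wettable"
                else "not wettable"))
  if (!is.na(object@intraPorosity) && object@intraPorosity > 0)
    cat(sprintf("  intraparticular porosity %.2f %%\n",
                object@intraPorosity))
  invisible(object)
})
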