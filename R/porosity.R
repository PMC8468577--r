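# Porosity arithmetic linking gravimetric tablet data, the segmented
# image, and the sub-voxel (intraparticular) porosity handed to a voxel
# dissolution engine. All porosities are carried in percent (0-100).

#' Tablet porosity from geometry and composition
#'
#' One minus true volume over apparent volume: the true volume is the sum
#' of the component masses over their helium densities, the apparent
#' volume the cylinder pi (D/2)^2 h.
#' \deqn{\phi_{tablet} = \left(1 - \frac{m_{API}/\rho_{API} +
#'   m_{ex}/\rho_{ex}}{\pi (D/2)^2 h}\right) \times 100\%}
#' Masses in mg with densities in kg/m^3 give volumes in mm^3 after a
#' factor 1000, consistent with D and h in mm.
#'
#' @param spec a [TabletSpec-class].
#' @param api,ex [Compound-class] objects providing the densities.
#' @return Tablet porosity in percent.
#' @examples
#' cmp <- defaultCompounds()
#' spec <- TabletSpec(11.28, 3.5, apiMass = 89.8, exMass = 320.4)
#' tabletPorosity(spec, cmp$api, cmp$ex)
#' @export
tabletPorosity <- function(spec, api, ex) {
  stopifnot(is(spec, "TabletSpec"), is(api, "Compound"),
            is(ex, "Compound"))
  trueVol <- 1000 * (spec@apiMass / api@density +
                     spec@exMass / ex@density)        # mm^3
  appVol <- pi * (spec@diameter / 2)^2 * spec@height  # mm^3
  phi <- (1 - trueVol / appVol) * 100
  if (phi < -5 || phi > 100)
    stop(sprintf(
      "non-physical tablet porosity %.1f %%: inconsistent inputs", phi))
  phi
}

#' Virtual excipient porosity for the dissolution calculation
#'
#' The difference between the measured tablet porosity and the porosity
#' visible in the segmented image is re-expressed as sub-voxel
#' (intraparticular) porosity of the excipient phase, the form a voxel
#' dissolution engine can consume:
#' \deqn{\phi_{ex} = \frac{S (\phi_{tablet} - \phi_{Image})
#'   Vx_{size} (Vx_{API} + Vx_{ex}) (1 + 0.01 \phi_{tablet})}{h\,Vx_{ex}}}
#' implemented literally as printed. A negative result (image porosity
#' exceeding the measured porosity, i.e. over-segmented voids) is returned
#' with a warning rather than an error.
#'
#' @param S slice count of the image stack.
#' @param phiTablet tablet porosity in percent (from [tabletPorosity()]).
#' @param phiImage image porosity in percent (from [imagePorosity()]).
#' @param vxSize voxel edge length in mm.
#' @param vxApi,vxEx voxel counts of API and excipient.
#' @param h tablet height in mm.
#' @return Assumed excipient porosity in percent.
#' @examples
#' excipientVirtualPorosity(S = 100, phiTablet = 12, phiImage = 9,
#'                          vxSize = 0.028, vxApi = 4e5, vxEx = 1.2e6,
#'                          h = 2.8)
#' @export
excipientVirtualPorosity <- function(S, phiTablet, phiImage, vxSize,
                                     vxApi, vxEx, h) {
  stopifnot(S >= 1, h > 0, vxEx >= 1, vxApi >= 0)
  if (phiTablet < 0 || phiTablet > 100 || phiImage < 0 || phiImage > 100)
    stop("porosities must lie in [0, 100] percent")
  phiEx <- S * (phiTablet - phiImage) * vxSize * (vxApi + vxEx) *
    (1 + 0.01 * phiTablet) / (h * vxEx)
  if (phiEx < 0)
    warning(sprintf(
      "negative virtual excipient porosity (%.2f %%): image porosity ",
      phiEx), "exceeds measured tablet porosity (over-segmented voids)")
  phiEx
}
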