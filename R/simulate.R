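# Reference dissolution fixture: a small, fully documented cellular
# automaton on the voxel grid. It exists so the validation harness has a
# transparent "tool under test" to exercise end-to-end; it is an original
# design and does NOT reproduce any proprietary dissolution engine.
#
# Update rule per time step dt:
#   1. Medium occupies every air voxel 6-connected to the bounding-box
#      faces, every fully dissolved voxel, and every permeated excipient
#      voxel (permeation below).
#   2. A wettable (contact angle < 90 deg) insoluble compound voxel with
#      intraparticular porosity phi > 0 starts a permeation countdown at
#      first medium contact: wettingTime / (0.01 * phi) seconds. When it
#      elapses, medium percolates through the voxel (the solid stays).
#      Unwettable or zero-porosity phases never permeate: drug enclosed by
#      them stays trapped (the non-percolation plateau signature).
#   3. Each soluble voxel in contact with medium loses mass at
#      rateConstant * solubility * exposedFaces * (1 + 6 * mixing) mg/s,
#      a perfect-sink surface-controlled rule. Dissolved mass accumulates
#      into the profile, sampled every samplingInterval seconds.

#' Construct a SimulationConfig
#'
#' Defaults mirror the conventional 12 h dissolution run: 43200 one-second
#' iterations, 600 s sampling, mixing parameter 0.05, pH 6.6 phosphate
#' buffer medium properties.
#'
#' @param compounds list of [Compound-class] covering every non-air label.
#' @param iterations number of time steps.
#' @param timeStep seconds per step.
#' @param samplingInterval seconds between profile samples.
#' @param mixingParameter dimensionless paddle-convection scaling in
#'   `[0, 1]`.
#' @param rateConstant intrinsic dissolution coefficient, mL per exposed
#'   voxel face per second.
#' @param wettingTime seconds to permeate a wettable voxel at 100%
#'   intraparticular porosity (scaled inversely with actual porosity).
#' @param mediumDensity,mediumViscosity,mediumTension medium properties
#'   (kg/m^3, Pa s, mN/m), recorded with the run.
#' @param seed integer seed recorded in the profile metadata.
#' @return A [SimulationConfig-class].
#' @examples
#' SimulationConfig(defaultCompounds(), iterations = 600L)
#' @export
SimulationConfig <- function(compounds, iterations = 43200L,
                             timeStep = 1, samplingInterval = 600,
                             mixingParameter = 0.05,
                             rateConstant = 1e-6, wettingTime = 600,
                             mediumDensity = 1007.0,
                             mediumViscosity = 0.0006865,
                             mediumTension = 67.9, seed = 1L) {
  new("SimulationConfig", compounds = unname(compounds),
      iterations = as.integer(iterations), timeStep = as.numeric(timeStep),
      samplingInterval = as.numeric(samplingInterval),
      mixingParameter = as.numeric(mixingParameter),
      rateConstant = as.numeric(rateConstant),
      wettingTime = as.numeric(wettingTime),
      mediumDensity = as.numeric(mediumDensity),
      mediumViscosity = as.numeric(mediumViscosity),
      mediumTension = as.numeric(mediumTension), seed = as.integer(seed))
}

#' Wettability check
#'
#' A compound is wettable by the medium iff its contact angle is strictly
#' below 90 degrees; at or above 90 degrees the medium cannot enter
#' through that phase. Compounds without a recorded contact angle (e.g.
#' the soluble API, which dissolves rather than wets) count as wettable.
#'
#' @param compounds list of [Compound-class] objects.
#' @return Named logical vector (names are compound names).
#' @examples
#' checkWettability(list(Compound(31L, "ec93", 1139.9, contactAngle = 93.2),
#'                       Compound(32L, "ec89", 1139.9, contactAngle = 89)))
#' @export
checkWettability <- function(compounds) {
  out <- vapply(compounds, function(cp)
    is.na(cp@contactAngle) || cp@contactAngle < 90, logical(1))
  names(out) <- vapply(compounds, function(cp) cp@name, character(1))
  out
}

.faceNeighborOffsets <- function(d) {
  # linear-index offsets and per-axis coordinate arrays for 6-connectivity
  S <- d[1L]; R <- d[2L]; C <- d[3L]
  n <- S * R * C
  i0 <- seq_len(n) - 1L
  s <- i0 %% S
  rest <- i0 %/% S
  r <- rest %% R
  cc <- rest %/% R
  list(s = s, r = r, cc = cc, S = S, R = R, C = C)
}

.exteriorAir <- function(lab, d, passable) {
  # voxels reachable from the bounding-box faces through passable voxels
  geo <- .faceNeighborOffsets(d)
  n <- length(lab)
  reach <- logical(n)
  onFace <- geo$s == 0L | geo$s == geo$S - 1L |
    geo$r == 0L | geo$r == geo$R - 1L |
    geo$cc == 0L | geo$cc == geo$C - 1L
  queue <- which(onFace & passable)
  reach[queue] <- TRUE
  .floodFrom(queue, reach, passable, d)
}

.floodFrom <- function(queue, reach, passable, d) {
  S <- d[1L]; R <- d[2L]
  while (length(queue)) {
    nxt <- integer(0)
    for (off in list(-1L, 1L, -S, S, -S * R, S * R)) {
      cand <- queue + off
      ok <- cand >= 1L & cand <= length(reach)
      # guard axis wrap-around: neighbour must differ in exactly the
      # stepped axis
      cand <- cand[ok]
      src <- queue[ok]
      if (abs(off) == 1L) {
        keep <- ((src - 1L) %/% S) == ((cand - 1L) %/% S)
      } else if (abs(off) == S) {
        keep <- ((src - 1L) %/% (S * R)) == ((cand - 1L) %/% (S * R))
      } else keep <- rep(TRUE, length(cand))
      cand <- cand[keep]
      cand <- cand[passable[cand] & !reach[cand]]
      if (length(cand)) {
        reach[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    queue <- unique(nxt)
  }
  reach
}

.mediumFaces <- function(idx, medium, d) {
  # number of medium-contact faces per voxel in idx; faces on the
  # bounding box count as medium (the tablet is immersed in the bath)
  S <- d[1L]; R <- d[2L]
  faces <- integer(length(idx))
  for (off in list(-1L, 1L, -S, S, -S * R, S * R)) {
    cand <- idx + off
    ok <- cand >= 1L & cand <= length(medium)
    if (abs(off) == 1L) {
      ok[ok] <- ((idx[ok] - 1L) %/% S) == ((cand[ok] - 1L) %/% S)
    } else if (abs(off) == S) {
      ok[ok] <- ((idx[ok] - 1L) %/% (S * R)) ==
        ((cand[ok] - 1L) %/% (S * R))
    }
    faces[!ok] <- faces[!ok] + 1L              # out of grid: bath contact
    faces[ok] <- faces[ok] + as.integer(medium[cand[ok]])
  }
  faces
}

#' Simulate dissolution of a voxel matrix (reference fixture)
#'
#' Runs the package's transparent cellular-automaton dissolution rule (see
#' the source header and the methods vignette) on a labelled voxel matrix
#' and returns the cumulative release profile of the soluble phase,
#' sampled every `samplingInterval` seconds. The rule is deterministic;
#' the config seed is provenance only. Output is labelled a reference
#' fixture: it stands in for an engine under test and reproduces no
#' commercial software.
#'
#' @param matrix a [VoxelMatrix-class].
#' @param config a [SimulationConfig-class] whose compounds cover every
#'   non-air, non-medium label present.
#' @return A [DissolutionProfile-class] (times in minutes); metadata-like
#'   attributes `initialApiMass` (mg) and `remainingApiMass` (mg) support
#'   mass-balance checks.
#' @examples
#' cmp <- defaultCompounds()
#' lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1L
#' m <- VoxelMatrix(lab, 0.1)
#' cfg <- SimulationConfig(cmp, iterations = 2000L, samplingInterval = 60)
#' simulateDissolution(m, cfg)
#' @export
simulateDissolution <- function(matrix, config) {
  stopifnot(is(matrix, "VoxelMatrix"), is(config, "SimulationConfig"))
  d <- dim(matrix@labels)
  lab <- as.integer(matrix@labels)
  ids <- vapply(config@compounds, function(cp) cp@id, integer(1))
  roles <- matrix@labelMap
  airIds <- as.integer(names(roles)[roles == "air"])
  mediumIds <- as.integer(names(roles)[roles == "medium"])
  cmpLabels <- as.integer(names(roles)[roles == "compound"])
  present <- intersect(unique(lab), cmpLabels)
  uncovered <- setdiff(present, ids)
  if (length(uncovered))
    stop("no Compound in the config for grey value(s) ",
         paste(uncovered, collapse = ", "))
  byId <- config@compounds[match(present, ids)]
  sol <- vapply(byId, function(cp) cp@solubility, numeric(1))
  if (!any(sol > 0))
    stop("no soluble compound present: nothing can dissolve")
  wet <- checkWettability(byId)
  poro <- vapply(byId, function(cp)
    ifelse(is.na(cp@intraPorosity), 0, cp@intraPorosity), numeric(1))

  vox <- matrix@voxelEdge^3 * 1e-3             # mm^3 -> voxel mass factor
  solubleIds <- present[sol > 0]
  permIds <- present[sol <= 0 & wet & poro > 0]
  permTime <- structure(
    config@wettingTime / (0.01 * pmax(poro[sol <= 0 & wet & poro > 0],
                                      1e-12)),
    names = as.character(permIds))
  solTab <- structure(sol[sol > 0], names = as.character(solubleIds))
  denTab <- structure(
    vapply(byId, function(cp) cp@density, numeric(1)),
    names = as.character(present))

  n <- length(lab)
  isSoluble <- lab %in% solubleIds
  mass <- numeric(n)
  mass[isSoluble] <- vox * denTab[as.character(lab[isSoluble])]
  initialApi <- sum(mass)

  passable <- lab %in% c(airIds, mediumIds)
  medium <- .exteriorAir(lab, d, passable)
  permCountdown <- rep(NA_real_, n)            # seconds until permeated
  permeated <- logical(n)

  dt <- config@timeStep
  steps <- config@iterations
  sampleEvery <- max(1L, as.integer(round(config@samplingInterval / dt)))
  rate0 <- config@rateConstant * (1 + 6 * config@mixingParameter)

  released <- 0
  times <- numeric(0)
  prof <- numeric(0)
  openMedium <- function(newIdx) {
    # newly opened voxels become medium; flood to any passable voxels
    # they connect (air pockets, permeated shells)
    newIdx <- newIdx[!medium[newIdx]]
    if (!length(newIdx)) return(medium)
    medium[newIdx] <- TRUE
    canPass <- passable | permeated
    .floodFrom(newIdx, medium, canPass, d)
  }

  for (step in seq_len(steps)) {
    # permeation countdowns for wettable insoluble porous voxels
    if (length(permIds)) {
      permIdx <- which(lab %in% permIds & !permeated)
      if (length(permIdx)) {
        contact <- .mediumFaces(permIdx, medium, d) > 0
        starting <- permIdx[contact & is.na(permCountdown[permIdx])]
        permCountdown[starting] <-
          permTime[as.character(lab[starting])]
        ticking <- permIdx[!is.na(permCountdown[permIdx])]
        permCountdown[ticking] <- permCountdown[ticking] - dt
        done <- ticking[permCountdown[ticking] <= 0]
        if (length(done)) {
          permeated[done] <- TRUE
          adj <- done[.mediumFaces(done, medium, d) > 0]
          if (length(adj)) medium <- openMedium(adj)
        }
      }
    }
    # dissolution of soluble voxels in medium contact
    solIdx <- which(isSoluble & mass > 0)
    if (length(solIdx)) {
      faces <- .mediumFaces(solIdx, medium, d)
      active <- solIdx[faces > 0]
      if (length(active)) {
        rate <- rate0 * solTab[as.character(lab[active])] *
          faces[faces > 0]
        dm <- pmin(mass[active], rate * dt)
        mass[active] <- mass[active] - dm
        released <- released + sum(dm)
        gone <- active[mass[active] <= 0]
        if (length(gone)) {
          isSoluble[gone] <- FALSE
          passable[gone] <- TRUE
          adj <- gone[.mediumFaces(gone, medium, d) > 0]
          if (length(adj)) medium <- openMedium(adj)
        }
      }
    }
    if (step %% sampleEvery == 0L) {
      times <- c(times, step * dt / 60)        # minutes
      prof <- c(prof, 100 * released / initialApi)
    }
  }
  out <- DissolutionProfile(times, prof,
                            label = "reference fixture simulation")
  attr(out, "initialApiMass") <- initialApi
  attr(out, "remainingApiMass") <- sum(mass)
  attr(out, "seed") <- config@seed
  out
}
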