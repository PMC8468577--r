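# Virtual tablet construction: random voxel placement ("distributed"),
# seeded 6-connected cluster growth ("seed_grow"), and densification to
# zero interparticular porosity. All randomness flows through one seed and
# the achieved composition is recorded as ground truth in the metadata.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

.voxelMass <- function(edge, density) edge^3 * density * 1e-3  # mg

.neighbors6 <- function(i, d) {
  S <- d[1L]; R <- d[2L]
  i0 <- i - 1L
  s <- i0 %% S
  rest <- i0 %/% S
  r <- rest %% R
  cc <- rest %/% R
  out <- integer(0)
  if (s > 0L) out <- c(out, i - 1L)
  if (s < S - 1L) out <- c(out, i + 1L)
  if (r > 0L) out <- c(out, i - S)
  if (r < R - 1L) out <- c(out, i + S)
  if (cc > 0L) out <- c(out, i - S * R)
  if (cc < d[3L] - 1L) out <- c(out, i + S * R)
  out
}

#' Construct GenerationParams
#'
#' @param dim grid dimensions (slices, rows, cols).
#' @param voxelEdge voxel edge length in mm.
#' @param diameter,height cylinder dimensions in mm; the cylinder must fit
#'   inside the grid.
#' @param targets named numeric vector of target masses in mg; names must
#'   match compound names.
#' @param mode `"distributed"` or `"seed_grow"`.
#' @param nSeeds seeds per compound (seed_grow only); controls the number
#'   of particles, while the growth to target mass controls their size.
#' @param seed integer RNG seed.
#' @return A [GenerationParams-class] object.
#' @examples
#' GenerationParams(c(20, 40, 40), 0.1, 3.5, 1.8,
#'                  targets = c(theophylline = 4, `ethyl cellulose` = 8))
#' @export
GenerationParams <- function(dim, voxelEdge, diameter, height, targets,
                             mode = c("distributed", "seed_grow"),
                             nSeeds = 1L, seed = 1L) {
  mode <- match.arg(mode)
  new("GenerationParams", dim = as.integer(dim),
      voxelEdge = as.numeric(voxelEdge), diameter = as.numeric(diameter),
      height = as.numeric(height), targets = targets, mode = mode,
      nSeeds = as.integer(nSeeds), seed = as.integer(seed))
}

.targetCounts <- function(params, compounds) {
  ids <- vapply(compounds, function(cp) cp@id, integer(1))
  nms <- vapply(compounds, function(cp) cp@name, character(1))
  if (!all(names(params@targets) %in% nms))
    stop("target names must match compound names; unknown: ",
         paste(setdiff(names(params@targets), nms), collapse = ", "))
  vm <- .voxelMass(params@voxelEdge,
                   vapply(compounds, function(cp) cp@density, numeric(1)))
  names(vm) <- nms
  tg <- params@targets[nms]
  tg[is.na(tg)] <- 0
  counts <- as.integer(round(tg / vm))
  list(ids = ids, names = nms, counts = counts, voxelMass = vm)
}

.generationResult <- function(lab, params, tc, mask, nSeeds = NULL) {
  d <- params@dim
  labels <- array(lab, d)
  lmap <- defaultLabelMap()
  extra <- setdiff(as.character(tc$ids), names(lmap))
  if (length(extra)) {
    add <- rep("compound", length(extra))
    names(add) <- extra
    lmap <- c(lmap, add)
  }
  achieved <- tc$counts * tc$voxelMass
  gt <- list(counts = structure(tc$counts, names = tc$names),
             masses = structure(achieved, names = tc$names),
             airFractionCylinder = sum(lab[mask] == 0L) / sum(mask))
  VoxelMatrix(labels, voxelEdge = params@voxelEdge, labelMap = lmap,
              metadata = list(mode = params@mode, seed = params@seed,
                              diameter = params@diameter,
                              height = params@height,
                              targets = params@targets,
                              nSeeds = nSeeds, groundTruth = gt))
}

#' Generate a virtual tablet by random voxel placement
#'
#' In-cylinder voxels are assigned uniformly at random to the compounds
#' until each compound's mass is within one voxel-mass of its target;
#' remaining in-cylinder voxels (and everything outside the cylinder) stay
#' air. Deterministic given the seed in `params`.
#'
#' @param params a [GenerationParams-class].
#' @param compounds list of [Compound-class] objects.
#' @return A [VoxelMatrix-class] with ground-truth bookkeeping (achieved
#'   voxel counts, masses, in-cylinder air fraction) in its metadata.
#' @seealso [generateSeedGrow()], [densify()]
#' @examples
#' p <- GenerationParams(c(10, 20, 20), 0.1, 1.6, 0.8,
#'                       targets = c(theophylline = 0.6,
#'                                   `ethyl cellulose` = 0.9))
#' m <- generateDistributed(p, defaultCompounds()[1:2])
#' voxelCounts(m)
#' @export
generateDistributed <- function(params, compounds) {
  stopifnot(is(params, "GenerationParams"))
  tc <- .targetCounts(params, compounds)
  d <- params@dim
  mask <- .cylinderMask(d, params@voxelEdge, params@diameter,
                        params@height)
  cells <- which(mask)
  if (sum(tc$counts) > length(cells))
    stop(sprintf(
      "infeasible targets: %d solid voxels required but the cylinder %s",
      sum(tc$counts),
      sprintf("holds only %d voxels", length(cells))))
  lab <- integer(prod(d))
  .withSeed(params@seed, {
    chosen <- sample(cells, sum(tc$counts))
    at <- 0L
    for (k in seq_along(compounds)) {
      n <- tc$counts[k]
      if (n > 0L) lab[chosen[at + seq_len(n)]] <- tc$ids[k]
      at <- at + n
    }
  })
  .generationResult(lab, params, tc, mask)
}

#' Generate a virtual tablet by seeding and growing clusters
#'
#' `nSeeds` voxels per compound are placed uniformly at random inside the
#' cylinder; growth proceeds in rounds, each round accreting one
#' uniformly-chosen empty 6-neighbour voxel per surviving cluster per
#' compound, until that compound's target mass is reached (within one
#' voxel-mass). The seed count controls particle number, the growth
#' controls particle size; clusters are 6-connected by construction.
#'
#' @inheritParams generateDistributed
#' @return A [VoxelMatrix-class] with ground-truth metadata.
#' @examples
#' p <- GenerationParams(c(10, 20, 20), 0.1, 1.6, 0.8,
#'                       targets = c(theophylline = 0.4,
#'                                   `ethyl cellulose` = 0.6),
#'                       mode = "seed_grow", nSeeds = 3L)
#' m <- generateSeedGrow(p, defaultCompounds()[1:2])
#' @export
generateSeedGrow <- function(params, compounds) {
  stopifnot(is(params, "GenerationParams"))
  if (params@mode != "seed_grow")
    params@mode <- "seed_grow"
  tc <- .targetCounts(params, compounds)
  d <- params@dim
  mask <- .cylinderMask(d, params@voxelEdge, params@diameter,
                        params@height)
  cells <- which(mask)
  if (sum(tc$counts) > length(cells))
    stop(sprintf("infeasible targets: %d solid voxels required but the ",
                 sum(tc$counts)),
         sprintf("cylinder holds only %d voxels", length(cells)))
  nSeeds <- rep_len(params@nSeeds, length(compounds))
  nSeeds <- pmin(nSeeds, tc$counts)       # zero-growth degenerate case
  lab <- integer(prod(d))
  inMask <- logical(prod(d)); inMask[cells] <- TRUE
  .withSeed(params@seed, {
    seedCells <- sample(cells, sum(nSeeds))
    at <- 0L
    placed <- integer(length(compounds))
    clusters <- vector("list", length(compounds))
    for (k in seq_along(compounds)) {
      sc <- seedCells[at + seq_len(nSeeds[k])]
      at <- at + nSeeds[k]
      lab[sc] <- tc$ids[k]
      placed[k] <- nSeeds[k]
      clusters[[k]] <- lapply(sc, function(i) {
        nb <- .neighbors6(i, d)
        list(frontier = nb[inMask[nb] & lab[nb] == 0L], alive = TRUE)
      })
    }
    while (any(placed < tc$counts)) {
      progressed <- FALSE
      for (k in seq_along(compounds)) {
        if (placed[k] >= tc$counts[k]) next
        for (ci in seq_along(clusters[[k]])) {
          if (placed[k] >= tc$counts[k]) break
          cl <- clusters[[k]][[ci]]
          if (!cl$alive) next
          idx <- NA_integer_
          while (length(cl$frontier)) {
            j <- if (length(cl$frontier) == 1L) 1L
                 else sample.int(length(cl$frontier), 1L)
            cand <- cl$frontier[j]
            cl$frontier <- cl$frontier[-j]
            if (lab[cand] == 0L) { idx <- cand; break }
          }
          if (is.na(idx)) {
            cl$alive <- FALSE
            clusters[[k]][[ci]] <- cl
            next
          }
          lab[idx] <- tc$ids[k]
          placed[k] <- placed[k] + 1L
          nb <- .neighbors6(idx, d)
          cl$frontier <- c(cl$frontier,
                           nb[inMask[nb] & lab[nb] == 0L])
          clusters[[k]][[ci]] <- cl
          progressed <- TRUE
        }
        if (placed[k] < tc$counts[k] &&
            !any(vapply(clusters[[k]], `[[`, logical(1), "alive")))
          stop(sprintf(
            "compound '%s' is fully enclosed: %d voxels placed of %d",
            tc$names[k], placed[k], tc$counts[k]))
      }
      if (!progressed && any(placed < tc$counts)) {
        k <- which(placed < tc$counts)[1L]
        stop(sprintf(
          "compound '%s' is fully enclosed: %d voxels placed of %d",
          tc$names[k], placed[k], tc$counts[k]))
      }
    }
  })
  .generationResult(lab, params, tc, mask, nSeeds = nSeeds)
}

#' Densify a virtual tablet to zero interparticular porosity
#'
#' Converts in-cylinder air voxels to compound voxels, keeping the
#' compound voxel-count ratio constant to within one voxel, so that the
#' in-cylinder interparticular porosity becomes 0. Pre-existing compound
#' voxels are never touched. With `mode = "distributed"` the air voxels
#' are reassigned uniformly at random; with `mode = "seed_grow"` each
#' compound accretes air voxels adjacent to its own phase (falling back to
#' random air voxels if its surface is exhausted).
#'
#' Voxel-count ratio (not mass ratio) is the preserved quantity: it is
#' what a voxel engine can hold exactly when densities differ. The mass
#' ratio is reported in the metadata alongside.
#'
#' @param matrix a [VoxelMatrix-class]; a generated matrix carries its
#'   cylinder geometry in metadata, otherwise supply `diameter`/`height`
#'   (or the full grid is used).
#' @param mode `"distributed"` or `"seed_grow"`.
#' @param seed RNG seed for the reassignment.
#' @param diameter,height optional cylinder geometry in mm.
#' @return A densified [VoxelMatrix-class].
#' @examples
#' p <- GenerationParams(c(8, 16, 16), 0.1, 1.2, 0.6,
#'                       targets = c(theophylline = 0.2,
#'                                   `ethyl cellulose` = 0.3))
#' dense <- densify(generateDistributed(p, defaultCompounds()[1:2]))
#' imagePorosity(dense, region = "cylinder")
#' @export
densify <- function(matrix, mode = c("distributed", "seed_grow"),
                    seed = 1L, diameter = NULL, height = NULL) {
  stopifnot(is(matrix, "VoxelMatrix"))
  mode <- match.arg(mode)
  d <- dim(matrix@labels)
  md <- matrix@metadata
  if (is.null(diameter)) diameter <- md$diameter
  if (is.null(height)) height <- md$height
  mask <- if (is.null(diameter) || is.null(height)) {
    array(TRUE, d)
  } else {
    .cylinderMask(d, matrix@voxelEdge, diameter, height)
  }
  airIds <- as.integer(names(matrix@labelMap)[matrix@labelMap == "air"])
  cmpIds <- as.integer(names(matrix@labelMap)[
    matrix@labelMap == "compound"])
  lab <- as.vector(matrix@labels)
  inMask <- as.vector(mask)
  counts <- vapply(cmpIds, function(id) sum(lab == id & inMask),
                   numeric(1))
  present <- cmpIds[counts > 0]
  counts <- counts[counts > 0]
  if (length(present) < 1L)
    stop("matrix contains no compound voxels inside the region")
  airCells <- which(inMask & lab %in% airIds)
  if (!length(airCells)) return(matrix)      # already dense: idempotent
  # largest-remainder apportionment keeps the voxel-count ratio within 1
  nAir <- length(airCells)
  exact <- counts / sum(counts) * nAir
  add <- floor(exact)
  rem <- nAir - sum(add)
  if (rem > 0) {
    ord <- order(exact - add, decreasing = TRUE)
    add[ord[seq_len(rem)]] <- add[ord[seq_len(rem)]] + 1
  }
  .withSeed(seed, {
    if (mode == "distributed") {
      shuffled <- sample(airCells)
      at <- 0L
      for (k in seq_along(present)) {
        if (add[k] > 0) lab[shuffled[at + seq_len(add[k])]] <- present[k]
        at <- at + add[k]
      }
    } else {
      isAir <- logical(length(lab)); isAir[airCells] <- TRUE
      frontiers <- lapply(present, function(id) {
        own <- which(lab == id & inMask)
        nb <- unlist(lapply(own, .neighbors6, d = d))
        unique(nb[isAir[nb]])
      })
      left <- add
      while (any(left > 0)) {
        for (k in seq_along(present)) {
          if (left[k] <= 0) next
          fr <- frontiers[[k]]
          idx <- NA_integer_
          while (length(fr)) {
            j <- if (length(fr) == 1L) 1L else sample.int(length(fr), 1L)
            cand <- fr[j]
            fr <- fr[-j]
            if (isAir[cand]) { idx <- cand; break }
          }
          if (is.na(idx)) {                  # surface exhausted: fallback
            pool <- which(isAir)
            idx <- if (length(pool) == 1L) pool
                   else pool[sample.int(length(pool), 1L)]
          }
          lab[idx] <- present[k]
          isAir[idx] <- FALSE
          left[k] <- left[k] - 1L
          nb <- .neighbors6(idx, d)
          fr <- c(fr, nb[isAir[nb]])
          frontiers[[k]] <- fr
        }
      }
    }
  })
  newCounts <- vapply(present, function(id) sum(lab == id & inMask),
                      numeric(1))
  out <- matrix
  out@labels <- array(as.integer(lab), d)
  out@metadata$densified <- list(mode = mode, seed = seed,
                                 countsBefore = counts,
                                 countsAfter = newCounts)
  out
}
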