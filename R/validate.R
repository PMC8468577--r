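# Batch validation: one record per predicted profile, comparing it to the
# experimental reference by f1/f2 and by Higuchi / Korsmeyer-Peppas
# regression equality, in the long report layout (one row per matrix and
# model; NA printed literally where a value was not calculated).

.asProfile <- function(x, label = NULL) {
  if (is(x, "DissolutionProfile")) x
  else if (is.character(x) && length(x) == 1L)
    readProfile(x, label = if (is.null(label)) basename(x) else label)
  else stop("expected a DissolutionProfile or a CSV path")
}

.fitBoth <- function(profile, lo, hi) {
  list(higuchi = fitHiguchi(profile, lo, hi),
       korsmeyer_peppas = fitKorsmeyerPeppas(profile, lo, hi))
}

.kineticRow <- function(label, model, desirability, sim, fitP, fitR,
                        alpha) {
  row <- data.frame(
    matrix = label, model = model, desirability = desirability,
    f1 = sim@f1, f2 = sim@f2, slope = NA_real_, intercept = NA_real_,
    r2 = NA_real_, adj_r2 = NA_real_, p_slope = NA_real_,
    p_intercept = NA_real_, similar = sim@verdict, excluded = FALSE,
    note = "", stringsAsFactors = FALSE)
  if (isExcluded(fitP)) {
    row$excluded <- TRUE
    row$note <- fitP$reason
    return(row)
  }
  row$slope <- fitP@slope
  row$intercept <- fitP@intercept
  row$r2 <- fitP@r2
  row$adj_r2 <- fitP@adjR2
  if (isExcluded(fitR)) {
    row$note <- paste("reference profile excluded:", fitR$reason)
    return(row)
  }
  cmp <- compareRegressions(fitP, fitR, alpha = alpha)
  row$p_slope <- cmp@pSlope
  row$p_intercept <- cmp@pIntercept
  row
}

#' Run the profile validation pipeline over a batch of predictions
#'
#' For each prediction (a profile, a profile CSV path, or a voxel matrix
#' to be simulated with the reference fixture): select paired points
#' against the experimental profile, compute f1/f2 and the similarity
#' verdict, fit Higuchi and Korsmeyer-Peppas kinetics on the 20-60%
#' window (excluding profiles with fewer than 4 window points), and test
#' slope/intercept equality against the experimental fits. Failures of
#' one prediction are recorded in its rows, not fatal to the batch.
#'
#' @param experimental [DissolutionProfile-class] or CSV path.
#' @param predictions named list of predictions; a [VoxelMatrix-class]
#'   element is simulated via [simulateDissolution()] with `config`.
#' @param desirabilities optional named numeric vector of tablet
#'   desirabilities, matched to prediction names.
#' @param config [SimulationConfig-class], required when matrices are
#'   among the predictions.
#' @param tMax,releaseCut,includeZero forwarded to [selectPoints()].
#' @param limitF1,limitF2 similarity limits.
#' @param lo,hi kinetic window bounds in percent released.
#' @param alpha significance level of the regression tests.
#' @return A data.frame, two rows per prediction (model `"higuchi"` then
#'   `"korsmeyer_peppas"`) with columns `matrix`, `model`,
#'   `desirability`, `f1`, `f2`, `slope`, `intercept`, `r2`, `adj_r2`,
#'   `p_slope`, `p_intercept`, `similar`, `excluded`, `note`.
#' @seealso [writeValidationCsv()], [summarizeReplicates()]
#' @examples
#' ref <- synthProfile("square_root", k = 2)
#' pred <- synthProfile("power_law", k = 1.2, n = 0.55)
#' runValidation(ref, list(example = pred))
#' @export
runValidation <- function(experimental, predictions, desirabilities = NULL,
                          config = NULL, tMax = 720, releaseCut = 99.5,
                          includeZero = FALSE, limitF1 = 15,
                          limitF2 = 50, lo = 20, hi = 60, alpha = 0.05) {
  ref <- .asProfile(experimental, label = "experimental")
  refFits <- .fitBoth(ref, lo, hi)
  if (is.null(names(predictions)))
    names(predictions) <- paste0("prediction_", seq_along(predictions))
  rows <- list()
  for (nm in names(predictions)) {
    des <- if (!is.null(desirabilities) && nm %in% names(desirabilities))
      desirabilities[[nm]] else NA_real_
    rec <- tryCatch({
      p <- predictions[[nm]]
      prof <- if (is(p, "VoxelMatrix")) {
        if (is.null(config))
          stop("a SimulationConfig is required to simulate matrices")
        simulateDissolution(p, config)
      } else .asProfile(p, label = nm)
      sim <- compareProfiles(ref, prof, tMax = tMax,
                             releaseCut = releaseCut,
                             includeZero = includeZero,
                             limitF1 = limitF1, limitF2 = limitF2)
      fits <- .fitBoth(prof, lo, hi)
      rbind(
        .kineticRow(nm, "higuchi", des, sim, fits$higuchi,
                    refFits$higuchi, alpha),
        .kineticRow(nm, "korsmeyer_peppas", des, sim,
                    fits$korsmeyer_peppas, refFits$korsmeyer_peppas,
                    alpha))
    }, error = function(e) {
      data.frame(matrix = nm, model = c("higuchi", "korsmeyer_peppas"),
                 desirability = des, f1 = NA_real_, f2 = NA_real_,
                 slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                 adj_r2 = NA_real_, p_slope = NA_real_,
                 p_intercept = NA_real_, similar = NA,
                 excluded = FALSE,
                 note = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[nm]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a validation report CSV
#'
#' Serialises the record table of [runValidation()]; values that were not
#' calculated are printed as the literal string `NA`.
#'
#' @param records data.frame from [runValidation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeValidationCsv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Pointwise mean and standard deviation of replicate profiles
#'
#' Replicate dissolution profiles (equal time grids required) are
#' summarised as the pointwise mean and sample standard deviation, the
#' conventional x-bar +/- SD presentation for n = 3 tablets.
#'
#' @param profiles list of [DissolutionProfile-class] objects.
#' @return A data.frame with columns `time_min`, `mean_pct`, `sd_pct`
#'   (`sd_pct` is `NA` for a single replicate) and attribute `n`.
#' @examples
#' p1 <- synthProfile("square_root", k = 2, noiseSd = 1, seed = 1)
#' p2 <- synthProfile("square_root", k = 2, noiseSd = 1, seed = 2)
#' head(summarizeReplicates(list(p1, p2)))
#' @export
summarizeReplicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "DissolutionProfile")))
  times <- profiles[[1L]]@times
  for (p in profiles[-1L])
    if (length(p@times) != length(times) || any(p@times != times))
      stop("replicate profiles must share one time grid")
  mat <- vapply(profiles, function(p) p@released,
                numeric(length(times)))
  mat <- matrix(mat, nrow = length(times))
  out <- data.frame(
    time_min = times,
    mean_pct = rowMeans(mat),
    sd_pct = if (length(profiles) > 1L) apply(mat, 1L, stats::sd)
             else NA_real_)
  attr(out, "n") <- length(profiles)
  out
}
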