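#' @include protocols.R
NULL

.MODULE_OUTPUT_MARKERS <- list(
  inflammation = c("IL6", "IL1b", "CCL2"),
  growth = c("Ang2", "SEMA3G", "BDNF"),
  tight_junction = c("ZO1", "Claudin5"))

.normalizedMarkers <- function(traj, markers, baseline) {
  missing <- setdiff(markers, colnames(traj@amounts))
  if (length(missing))
    stop("trajectory lacks required marker(s): ",
         paste(missing, collapse = ", "))
  bad <- markers[!(markers %in% names(baseline)) | baseline[markers] <= 0]
  if (length(bad))
    stop("normalization error: nonpositive or missing baseline for ",
         paste(bad, collapse = ", "))
  sweep(traj@amounts[, markers, drop = FALSE], 2, baseline[markers], "/")
}

#' Pathway module output of a trajectory
#'
#' Elementwise product of normalized marker series: inflammation =
#' IL-6 * IL-1b * CCL2; growth = Ang2 * SEMA3G * BDNF; tight_junction =
#' ZO-1 * Claudin5. Each marker is divided by its control baseline before
#' multiplication.
#'
#' @param traj a Trajectory.
#' @param which "inflammation", "growth" or "tight_junction".
#' @param baseline named numeric control values (default: the trajectory's
#'   state at stimulus start).
#' @return numeric vector over the trajectory's time grid.
#' @export
moduleOutput <- function(traj, which = c("inflammation", "growth",
                                         "tight_junction"),
                         baseline = stimulusBaseline(traj)) {
  which <- match.arg(which)
  m <- .normalizedMarkers(traj, .MODULE_OUTPUT_MARKERS[[which]], baseline)
  apply(m, 1, prod)
}

#' Cell-function score series of a trajectory
#'
#' Proliferation score = product of normalized Ang2, SEMA3G, BDNF, ZO-1,
#' Claudin5; damage score = product of normalized IL-6, IL-1b, CCL2, ROS,
#' ONOO-, Caspase3; cell function (CF) = proliferation / damage. All three
#' equal 1 at the control baseline.
#'
#' @param traj a Trajectory.
#' @param baseline named numeric control values for the 11 scored markers
#'   (> 0); defaults to the trajectory's state at stimulus start.
#' @return a \code{ScoreSeries}.
#' @export
cellFunctionScore <- function(traj, baseline = stimulusBaseline(traj)) {
  pm <- .normalizedMarkers(traj, proliferationMarkers(), baseline)
  dm <- .normalizedMarkers(traj, damageMarkers(), baseline)
  prolif <- apply(pm, 1, prod)
  damage <- apply(dm, 1, prod)
  used <- c(proliferationMarkers(), damageMarkers())
  new("ScoreSeries", times = traj@times, proliferation = prolif,
      damage = damage, cellFunction = prolif / damage,
      baseline = baseline[used])
}

#' Endpoint cell-function score
#' @param score a ScoreSeries.
#' @return CF value at the final timepoint.
#' @export
endpointCF <- function(score) {
  score@cellFunction[length(score@cellFunction)]
}

#' OGD x reoxygenation phenotype grid
#'
#' For each (OGD duration, reoxygenation duration) condition, runs the
#' OGD/R protocol from the quiescent state, samples the 12 functional
#' markers at the end of the reoxygenation period, normalizes to the
#' control baseline and log2-transforms. Default durations are OGD 1, 3,
#' 4, 6, 24 h and reoxygenation 1, 6, 12, 18, 24 h. Values below 1e-6 of
#' baseline are clipped before the log2 transform.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet.
#' @param ogdList,reoxList condition durations (hours; nonempty).
#' @param state quiescent starting state.
#' @param settings integration settings.
#' @return a \code{PhenotypeGrid}.
#' @export
phenotypeGrid <- function(network, params = defaultParameters(network),
                          ogdList = c(1, 3, 4, 6, 24),
                          reoxList = c(1, 6, 12, 18, 24),
                          state = initialState(network),
                          settings = simSettings()) {
  if (!length(ogdList) || !length(reoxList))
    stop("ogdList and reoxList must be nonempty")
  markers <- markerIds()
  vals <- matrix(NA_real_, length(markers),
                 length(ogdList) * length(reoxList),
                 dimnames = list(markers, NULL))
  cn <- character(ncol(vals))
  j <- 0L
  for (ogd in ogdList) for (rx in reoxList) {
    j <- j + 1L
    cn[j] <- sprintf("ogd%g_reox%g", ogd, rx)
    traj <- tryCatch(
      runProtocol(network, params, state, makeOGDRProtocol(ogd, rx),
                  settings),
      error = function(e)
        stop("phenotype grid cell ogd=", ogd, " reox=", rx, ": ",
             conditionMessage(e), call. = FALSE))
    baseline <- stimulusBaseline(traj)
    final <- traj@amounts[nrow(traj@amounts), markers]
    rel <- pmax(final / baseline[markers], 1e-6)
    vals[, j] <- log2(rel)
  }
  colnames(vals) <- cn
  new("PhenotypeGrid", markers = markers, ogdDurations = ogdList,
      reoxDurations = reoxList, values = vals)
}

#' Tidy data.frame view of a phenotype grid
#' @param grid a PhenotypeGrid.
#' @return data.frame(marker, ogd_h, reox_h, log2fc).
#' @export
gridToDataFrame <- function(grid) {
  conds <- expand.grid(reox_h = grid@reoxDurations,
                       ogd_h = grid@ogdDurations)[, c(2, 1)]
  out <- do.call(rbind, lapply(seq_along(grid@markers), function(i)
    data.frame(marker = grid@markers[i], ogd_h = conds$ogd_h,
               reox_h = conds$reox_h, log2fc = grid@values[i, ],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write a phenotype grid as tidy CSV
#' @param grid a PhenotypeGrid.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeGridCSV <- function(grid, file) {
  utils::write.csv(gridToDataFrame(grid), file, row.names = FALSE)
  invisible(file)
}
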