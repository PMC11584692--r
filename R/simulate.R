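#' @include rhs.R
NULL

#' Integration settings
#'
#' Stiff integration via \code{deSolve::lsoda} with relative tolerance
#' 1e-6 and absolute tolerance 1e-9 (species units). The output grid uses
#' a fine step near phase boundaries and a coarser step elsewhere.
#' Numerically negative values are clamped to zero after integration and
#' counted; more than \code{clampWarnFraction} clamped samples raises a
#' warning.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (species units).
#' @param fineStep output step (h) within \code{fineWindow} of a phase
#'   boundary.
#' @param coarseStep output step (h) elsewhere.
#' @param fineWindow width (h) of the refined window after each phase start.
#' @param clampWarnFraction warning threshold on the clamped-sample fraction.
#' @param maxsteps lsoda maximum internal steps per output interval.
#' @return settings list.
#' @export
simSettings <- function(rtol = 1e-6, atol = 1e-9, fineStep = 0.01,
                        coarseStep = 0.1, fineWindow = 1,
                        clampWarnFraction = 1e-3, maxsteps = 50000) {
  list(rtol = rtol, atol = atol, fineStep = fineStep,
       coarseStep = coarseStep, fineWindow = fineWindow,
       clampWarnFraction = clampWarnFraction, maxsteps = maxsteps)
}

.phaseGrid <- function(duration, settings) {
  fine <- seq(0, min(settings$fineWindow, duration), by = settings$fineStep)
  coarse <- seq(0, duration, by = settings$coarseStep)
  g <- sort(unique(round(c(fine, coarse, duration), 9)))
  g[length(g)] <- duration  # exact endpoint for phase handoff
  g
}

#' Simulate a network over one phase
#'
#' Integrates the assembled ODE system from \code{state0} for
#' \code{tEnd} hours with a stiff-capable solver. Clamped environment
#' species are held at their values in \code{state0}.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet or named numeric.
#' @param state0 named nonnegative initial state (defaults to the
#'   network's baseline state).
#' @param tEnd end time in hours (> 0).
#' @param settings see \code{\link{simSettings}}.
#' @param times optional explicit output grid (hours, starting at 0).
#' @return a \code{Trajectory}; its first row equals \code{state0}.
#' @export
simulateModel <- function(network, params = defaultParameters(network),
                          state0 = initialState(network), tEnd,
                          settings = simSettings(), times = NULL) {
  stopifnot(tEnd > 0)
  sp <- speciesIds(network)
  state0 <- state0[sp]
  if (anyNA(state0)) stop("state0 must cover all species")
  if (any(state0 < 0)) stop("state0 must be nonnegative")
  rhs <- assembleRHS(network, params)
  if (is.null(times)) times <- .phaseGrid(tEnd, settings)
  dfun <- function(t, y, p) list(rhs(y, t))
  out <- deSolve::lsoda(y = state0, times = times, func = dfun, parms = NULL,
                        rtol = settings$rtol, atol = settings$atol,
                        maxsteps = settings$maxsteps)
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1] < 0)
    stop("simulation error: solver failed at t = ",
         signif(max(out[, 1]), 4), " h")
  m <- out[, -1, drop = FALSE]
  colnames(m) <- sp
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("simulation error: non-finite amount for species ", sp[bad[2]],
         " at t = ", signif(out[bad[1], 1], 4), " h")
  }
  neg <- m < 0
  clamp <- sum(neg)
  if (clamp) {
    worst <- min(m[neg])
    m[neg] <- 0
    if (clamp / length(m) > settings$clampWarnFraction)
      warning(sprintf("%d negative samples clamped (worst %.3g)",
                      clamp, worst))
  }
  new("Trajectory", times = as.numeric(out[, 1]), amounts = m,
      phaseMarks = data.frame(time = 0, phase = "phase1",
                              stringsAsFactors = FALSE),
      clampCount = as.integer(clamp))
}

#' Extract one species' time course
#' @param traj a Trajectory.
#' @param species species id.
#' @return numeric vector over the trajectory's time grid.
#' @export
speciesSeries <- function(traj, species) {
  if (!species %in% colnames(traj@amounts))
    stop("trajectory lacks species: ", species)
  traj@amounts[, species]
}

#' Write a trajectory as tidy CSV
#'
#' Columns: time, species, amount, phase.
#' @param traj a Trajectory.
#' @param file output path.
#' @param species optional subset of species ids.
#' @return the file path, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, file, species = colnames(traj@amounts)) {
  marks <- traj@phaseMarks
  idx <- findInterval(traj@times, marks$time)
  idx[idx < 1] <- 1
  phase <- marks$phase[idx]
  df <- do.call(rbind, lapply(species, function(s)
    data.frame(time = traj@times, species = s, amount = traj@amounts[, s],
               phase = phase, stringsAsFactors = FALSE)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Tidy data.frame view of a trajectory
#' @param traj a Trajectory.
#' @param species optional subset of species ids.
#' @return data.frame(time, species, amount, phase).
#' @export
trajectoryToDataFrame <- function(traj, species = colnames(traj@amounts)) {
  marks <- traj@phaseMarks
  idx <- findInterval(traj@times, marks$time)
  idx[idx < 1] <- 1
  phase <- marks$phase[idx]
  do.call(rbind, lapply(species, function(s)
    data.frame(time = traj@times, species = s, amount = traj@amounts[, s],
               phase = phase, stringsAsFactors = FALSE)))
}
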