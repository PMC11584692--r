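#' @include quiescence.R
NULL

#' Convert a ligand dose to molecules per cell
#'
#' Converts an in-vitro dosing concentration (ng/ml) into a standardized
#' number of molecules per cell: total ligand molecules per unit volume
#' divided by the average number of cells per unit volume.
#'
#' @param concentration_ng_ml dose in ng/ml (> 0).
#' @param molecular_weight_g_mol ligand molecular weight in g/mol (> 0).
#' @param cells_per_ml culture density in cells/ml (> 0).
#' @return molecules per cell.
#' @examples
#' convertDose(50, 40000, 1e6)  # ~7.53e5 molecules per cell
#' @export
convertDose <- function(concentration_ng_ml, molecular_weight_g_mol,
                        cells_per_ml) {
  if (any(c(concentration_ng_ml, molecular_weight_g_mol, cells_per_ml) <= 0))
    stop("all dose-conversion inputs must be > 0")
  avogadro <- 6.02214076e23
  concentration_ng_ml * 1e-9 / molecular_weight_g_mol * avogadro /
    cells_per_ml
}

#' Build a protocol phase
#' @param label phase label.
#' @param duration hours (> 0).
#' @param environment list(O2_fraction, glucose_mmol_L); defaults to
#'   control conditions.
#' @param ligand_doses named numeric, molecules per cell added at phase
#'   start.
#' @return phase list.
#' @export
protocolPhase <- function(label, duration, environment = controlEnvironment(),
                          ligand_doses = numeric(0)) {
  list(label = label, duration = duration, environment = environment,
       ligand_doses = ligand_doses)
}

#' Assemble a stimulus protocol
#' @param ... phases from \code{\link{protocolPhase}}.
#' @param preEquilibration hours of control equilibration before phase 1.
#' @return a StimulusProtocol.
#' @export
stimulusProtocol <- function(..., preEquilibration = 24) {
  new("StimulusProtocol", phases = list(...),
      preEquilibration = preEquilibration)
}

#' Control-only protocol
#' @param hours duration under control environment.
#' @param preEquilibration pre-equilibration hours.
#' @return a StimulusProtocol.
#' @export
controlProtocol <- function(hours, preEquilibration = 24) {
  stimulusProtocol(protocolPhase("control", hours),
                   preEquilibration = preEquilibration)
}

#' Build an OGD/R protocol
#'
#' Phase 1: oxygen-glucose deprivation with O2 and glucose set close to
#' zero; phase 2: reoxygenation under control environment. Zero-duration
#' phases are omitted, so \code{makeOGDRProtocol(0, 24)} is a pure control
#' protocol.
#'
#' @param ogd_hours OGD duration (>= 0).
#' @param reox_hours reoxygenation duration (>= 0).
#' @param preEquilibration control hours before OGD.
#' @param deprived_O2 O2 fraction during OGD (default 0.001; a hard zero
#'   would create singular Michaelis terms).
#' @param deprived_glucose glucose (mmol/L) during OGD (default 0.05).
#' @return a StimulusProtocol.
#' @export
makeOGDRProtocol <- function(ogd_hours, reox_hours, preEquilibration = 24,
                             deprived_O2 = 0.001, deprived_glucose = 0.05) {
  if (ogd_hours < 0 || reox_hours < 0)
    stop("OGD and reoxygenation durations must be >= 0")
  phases <- list()
  if (ogd_hours > 0)
    phases <- c(phases, list(protocolPhase("OGD", ogd_hours,
      environment = list(O2_fraction = deprived_O2,
                         glucose_mmol_L = deprived_glucose))))
  if (reox_hours > 0)
    phases <- c(phases, list(protocolPhase("reoxygenation", reox_hours)))
  if (!length(phases))
    phases <- list(protocolPhase("control", 1e-6 + 1))  # degenerate guard
  new("StimulusProtocol", phases = phases,
      preEquilibration = preEquilibration)
}

#' Ligand stimulation protocol
#' @param doses named numeric, species id -> molecules per cell added at
#'   stimulus start.
#' @param hours observation duration.
#' @param preEquilibration control hours before the bolus.
#' @return a StimulusProtocol.
#' @export
ligandProtocol <- function(doses, hours, preEquilibration = 24) {
  stimulusProtocol(protocolPhase("stimulus", hours, ligand_doses = doses),
                   preEquilibration = preEquilibration)
}

#' Hypoxia protocol (low O2, normal glucose)
#' @param o2_fraction O2 fraction during the hypoxic phase.
#' @param hours duration.
#' @param preEquilibration control hours before hypoxia.
#' @return a StimulusProtocol.
#' @export
hypoxiaProtocol <- function(o2_fraction, hours, preEquilibration = 24) {
  stimulusProtocol(
    protocolPhase("hypoxia", hours,
                  environment = list(O2_fraction = o2_fraction,
                                     glucose_mmol_L =
                                       controlEnvironment()$glucose_mmol_L)),
    preEquilibration = preEquilibration)
}

#' Total duration of a protocol (excluding pre-equilibration)
#' @param protocol a StimulusProtocol.
#' @return hours.
#' @export
protocolDuration <- function(protocol) {
  sum(vapply(protocol@phases, `[[`, numeric(1), "duration"))
}

#' Run a multi-phase stimulus protocol
#'
#' Phases are integrated sequentially: the terminal state of phase k, with
#' phase k+1's environment settings applied to the clamped O2/glucose
#' inputs and ligand boluses added, is the initial state of phase k+1.
#' Time 0 of the returned trajectory is the start of the first stimulus
#' phase; the pre-equilibration segment is reported at negative times.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet or named numeric.
#' @param state quiescent starting state.
#' @param protocol a StimulusProtocol.
#' @param settings integration settings.
#' @param preEqParams parameters used during the pre-equilibration
#'   segment (default: \code{params}). Supplying the unperturbed
#'   parameters here models an acute intervention applied at stimulus
#'   onset.
#' @return a \code{Trajectory} with phase marks (including
#'   "pre_equilibration" when present).
#' @export
runProtocol <- function(network, params = defaultParameters(network),
                        state = initialState(network), protocol,
                        settings = simSettings(), preEqParams = params) {
  validObject(protocol)
  sp <- speciesIds(network)
  state <- state[sp]
  phases <- protocol@phases
  if (protocol@preEquilibration > 0)
    phases <- c(list(protocolPhase("pre_equilibration",
                                   protocol@preEquilibration)), phases)
  t0 <- -if (protocol@preEquilibration > 0) protocol@preEquilibration else 0
  times <- numeric(0)
  rows <- list()
  marks <- data.frame(time = numeric(0), phase = character(0),
                      stringsAsFactors = FALSE)
  clamp <- 0L
  cur <- state
  for (ph in phases) {
    env <- ph$environment
    if (!is.null(env$O2_fraction) && "O2" %in% sp)
      cur["O2"] <- env$O2_fraction
    if (!is.null(env$glucose_mmol_L) && "Glc" %in% sp)
      cur["Glc"] <- env$glucose_mmol_L
    if (length(ph$ligand_doses)) {
      unknown <- setdiff(names(ph$ligand_doses), sp)
      if (length(unknown))
        stop("phase ", ph$label, ": unknown dosed species ",
             paste(unknown, collapse = ", "))
      cur[names(ph$ligand_doses)] <- cur[names(ph$ligand_doses)] +
        ph$ligand_doses
    }
    marks <- rbind(marks, data.frame(time = t0, phase = ph$label,
                                     stringsAsFactors = FALSE))
    phaseParams <- if (identical(ph$label, "pre_equilibration"))
      preEqParams else params
    tr <- tryCatch(
      simulateModel(network, phaseParams, cur, ph$duration, settings),
      error = function(e)
        stop("phase ", ph$label, ": ", conditionMessage(e), call. = FALSE))
    # at phase boundaries keep the post-transition row (with environment
    # changes and ligand boluses applied), dropping the duplicated time
    if (length(times)) {
      times <- times[-length(times)]
      prev <- rows[[length(rows)]]
      rows[[length(rows)]] <- prev[-nrow(prev), , drop = FALSE]
    }
    times <- c(times, tr@times + t0)
    rows[[length(rows) + 1L]] <- tr@amounts
    clamp <- clamp + tr@clampCount
    cur <- tr@amounts[nrow(tr@amounts), ]
    t0 <- t0 + ph$duration
  }
  new("Trajectory", times = times, amounts = do.call(rbind, rows),
      phaseMarks = marks, clampCount = clamp)
}

#' State and baseline at stimulus start
#'
#' Returns the row of a protocol trajectory at time 0 (end of
#' pre-equilibration / start of the first stimulus phase), used as the
#' control baseline for normalization.
#' @param traj a Trajectory from \code{\link{runProtocol}}.
#' @return named numeric state.
#' @export
stimulusBaseline <- function(traj) {
  i <- which.min(abs(traj@times - 0))
  traj@amounts[i, ]
}
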