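#' @include AllClasses.R
NULL

#' Species identifiers of a network
#' @param object a ReactionNetwork.
#' @return character vector.
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))

#' @rdname speciesIds
#' @export
setMethod("speciesIds", "ReactionNetwork", function(object) object@species$id)

#' Reaction identifiers of a network
#' @param object a ReactionNetwork.
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "ReactionNetwork",
  function(object) vapply(object@reactions, `[[`, character(1), "id"))

#' Module label per reaction
#' @param object a ReactionNetwork.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ReactionNetwork", function(object) object@moduleLabels)

#' Baseline (literature-style quiescent) state of a network
#' @param object a ReactionNetwork.
#' @return named numeric vector of initial amounts.
#' @export
setGeneric("initialState", function(object) standardGeneric("initialState"))

#' @rdname initialState
#' @export
setMethod("initialState", "ReactionNetwork", function(object) {
  stats::setNames(object@species$baseline, object@species$id)
})

#' Default (balanced) parameter set of a network
#' @param object a ReactionNetwork.
#' @return a ParameterSet.
#' @export
setGeneric("defaultParameters", function(object) standardGeneric("defaultParameters"))

#' @rdname defaultParameters
#' @export
setMethod("defaultParameters", "ReactionNetwork",
  function(object) object@metadata$parameters)

#' Stoichiometry matrix (species x reactions)
#' @param object a ReactionNetwork.
#' @return integer matrix with species rows and reaction columns.
#' @export
setGeneric("stoichiometryMatrix",
  function(object) standardGeneric("stoichiometryMatrix"))

#' @rdname stoichiometryMatrix
#' @export
setMethod("stoichiometryMatrix", "ReactionNetwork", function(object) {
  ids <- speciesIds(object)
  N <- matrix(0L, length(ids), length(object@reactions),
              dimnames = list(ids, reactionIds(object)))
  for (j in seq_along(object@reactions)) {
    r <- object@reactions[[j]]
    for (s in names(r$reactants))
      N[s, j] <- N[s, j] - as.integer(r$reactants[[s]])
    for (s in names(r$products))
      N[s, j] <- N[s, j] + as.integer(r$products[[s]])
  }
  N
})

#' Parameter values
#' @param object a ParameterSet.
#' @export
setGeneric("parameterValues", function(object) standardGeneric("parameterValues"))

#' @rdname parameterValues
#' @export
setMethod("parameterValues", "ParameterSet", function(object) object@values)

#' Parameter bounds
#' @param object a ParameterSet.
#' @export
setGeneric("parameterBounds", function(object) standardGeneric("parameterBounds"))

#' @rdname parameterBounds
#' @export
setMethod("parameterBounds", "ParameterSet", function(object) object@bounds)

#' Sampling times of a trajectory
#' @param object a Trajectory (or ScoreSeries).
#' @export
setGeneric("trajectoryTimes", function(object) standardGeneric("trajectoryTimes"))

#' @rdname trajectoryTimes
#' @export
setMethod("trajectoryTimes", "Trajectory", function(object) object@times)

#' @rdname trajectoryTimes
#' @export
setMethod("trajectoryTimes", "ScoreSeries", function(object) object@times)

#' Amount matrix of a trajectory
#' @param object a Trajectory.
#' @export
setGeneric("amounts", function(object) standardGeneric("amounts"))

#' @rdname amounts
#' @export
setMethod("amounts", "Trajectory", function(object) object@amounts)

#' Phase boundary marks of a trajectory
#' @param object a Trajectory.
#' @export
setGeneric("phaseMarks", function(object) standardGeneric("phaseMarks"))

#' @rdname phaseMarks
#' @export
setMethod("phaseMarks", "Trajectory", function(object) object@phaseMarks)

#' Cell-function score vector
#' @param object a ScoreSeries.
#' @export
setGeneric("cellFunction", function(object) standardGeneric("cellFunction"))

#' @rdname cellFunction
#' @export
setMethod("cellFunction", "ScoreSeries", function(object) object@cellFunction)

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork with", nrow(object@species), "species and",
      length(object@reactions), "reactions\n")
  tab <- table(object@moduleLabels)
  cat("  modules:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet with", length(object@values), "rate constants\n")
})

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol:", length(object@phases), "phase(s),",
      "pre-equilibration", object@preEquilibration, "h\n")
  for (p in object@phases)
    cat(sprintf("  %-14s %6.2f h  O2=%.3f glc=%.2f mM%s\n", p$label,
                p$duration, p$environment$O2_fraction,
                p$environment$glucose_mmol_L,
                if (length(p$ligand_doses))
                  paste0("  +", paste(names(p$ligand_doses), collapse = ","))
                else ""))
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "timepoints x",
      ncol(object@amounts), "species, t in [",
      min(object@times), ",", max(object@times), "] h;",
      object@clampCount, "clamped values\n")
})

setMethod("show", "ScoreSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("ScoreSeries over [%g, %g] h; endpoint CF = %.4g\n",
              object@times[1], object@times[n], object@cellFunction[n]))
})

setMethod("show", "PhenotypeGrid", function(object) {
  cat("PhenotypeGrid:", length(object@markers), "markers x",
      ncol(object@values), "conditions (log2 fold change)\n")
})

setMethod("show", "SensitivityResult", function(object) {
  cat("SensitivityResult:", length(object@parameterIds), "parameters x",
      length(object@outputIds), "outputs; n =", object@nSamples, "\n")
})

setMethod("show", "VirtualCohort", function(object) {
  cat("VirtualCohort of", length(object@cells), "cells\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: objective %.6g after %d evaluations (%s)\n",
              object@objective, object@evaluations,
              if (object@converged) "converged" else "budget exhausted"))
})
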