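#' @import methods
NULL

.COMPARTMENTS <- c("cytosol", "nucleus", "ER", "mitochondrion", "membrane",
                   "medium", "environment")
.ROLE_TAGS <- c("ligand", "receptor", "kinase", "transcription_factor",
                "metabolite", "radical", "marker", "environment")
.RATE_KINDS <- c("mass_action", "hill_activation", "hill_inhibition",
                 "michaelis_menten", "zeroth_order_synthesis",
                 "first_order_decay")
.MODULES <- c("inflammation", "survival", "hypoxia", "metabolism",
              "oxidative_stress", "environment")

#' Canonical functional marker panel
#'
#' The 12 markers whose relative expression changes are tracked on the
#' OGD x reoxygenation phenotype grid: inflammatory cytokines/chemokine
#' (IL6, IL1b, CCL2), growth factors (Ang2, SEMA3G, BDNF), tight junction
#' proteins (ZO1, Claudin5), free radicals (ROS, ONOO), and apoptosis
#' markers (p53, Casp3).
#' @return Character vector of species ids.
#' @export
markerIds <- function() {
  c("IL6", "IL1b", "CCL2", "Ang2", "SEMA3G", "BDNF",
    "ZO1", "Claudin5", "ROS", "ONOO", "p53", "Casp3")
}

#' Markers entering the proliferation score
#' @return Character vector of species ids.
#' @export
proliferationMarkers <- function() c("Ang2", "SEMA3G", "BDNF", "ZO1", "Claudin5")

#' Markers entering the damage score
#' @return Character vector of species ids.
#' @export
damageMarkers <- function() c("IL6", "IL1b", "CCL2", "ROS", "ONOO", "Casp3")

#' ParameterSet: positive rate constants with box bounds
#'
#' Holds one positive rate constant per reaction together with calibration
#' bounds; default bounds are 0.5x and 2x the baseline value.
#'
#' @slot values named numeric vector of positive rate constants (h^-1 base,
#'   adjusted for reaction order).
#' @slot bounds numeric matrix with columns \code{low}, \code{high} and one
#'   row per parameter.
#' @export
setClass("ParameterSet",
  representation(values = "numeric", bounds = "matrix"))

setValidity("ParameterSet", function(object) {
  v <- object@values
  b <- object@bounds
  if (is.null(names(v)) || anyDuplicated(names(v)))
    return("parameter values must have unique names")
  if (any(!is.finite(v)) || any(v <= 0))
    return("parameter values must be finite and positive")
  if (!identical(colnames(b), c("low", "high")))
    return("bounds must have columns 'low' and 'high'")
  if (!identical(rownames(b), names(v)))
    return("bounds rownames must match parameter names")
  if (any(b[, "low"] <= 0) || any(b[, "low"] > v + 1e-12) ||
      any(b[, "high"] < v - 1e-12))
    return("each value must satisfy 0 < low <= value <= high")
  TRUE
})

#' ReactionNetwork: species registry plus reaction list
#'
#' The mechanistic core: a species table, a list of reactions with rate
#' laws (mass action / Hill kinetics), per-reaction module labels, and
#' construction metadata (baseline parameters, designated balancing
#' parameters, clamped environment species).
#'
#' @slot species data.frame with columns id, compartment, baseline, unit,
#'   roles (comma-separated role tags).
#' @slot reactions list; each element has id, module, reactants (named
#'   numeric stoichiometry), products (named numeric), and law (kind,
#'   param, regulators).
#' @slot moduleLabels named character, reaction id -> module.
#' @slot balancers named character, species id -> parameter id solved
#'   during steady-state balancing.
#' @slot metadata list (default parameters, notes, counts).
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "list",
                 moduleLabels = "character", balancers = "character",
                 metadata = "list"))

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  rx <- object@reactions
  need <- c("id", "compartment", "baseline", "unit", "roles")
  if (!all(need %in% names(sp)))
    return("species table must have id/compartment/baseline/unit/roles")
  if (anyDuplicated(sp$id)) return("species ids must be unique")
  if (any(!sp$compartment %in% .COMPARTMENTS))
    return("unknown species compartment")
  if (any(sp$baseline < 0)) return("initial amounts must be >= 0")
  roles <- strsplit(sp$roles, ",", fixed = TRUE)
  bad <- setdiff(unlist(roles), c(.ROLE_TAGS, ""))
  if (length(bad)) return(paste("unknown role tag:", bad[1]))
  tagged <- sp$id[vapply(roles, function(r) "marker" %in% r, logical(1))]
  if (!all(tagged %in% markerIds()))
    return("species tagged 'marker' must belong to the canonical marker list")
  ids <- sp$id
  rids <- vapply(rx, `[[`, character(1), "id")
  if (anyDuplicated(rids)) return("reaction ids must be unique")
  participating <- character(0)
  for (r in rx) {
    if (!length(r$reactants) && !length(r$products))
      return(paste0("reaction ", r$id, ": reactants and products both empty"))
    refs <- c(names(r$reactants), names(r$products),
              vapply(r$law$regulators, `[[`, character(1), "species"))
    if (!all(refs %in% ids))
      return(paste0("reaction ", r$id, " references unknown species"))
    st <- c(r$reactants, r$products)
    if (length(st) && (any(st < 1) || any(st != round(st))))
      return(paste0("reaction ", r$id, ": stoichiometries must be integers >= 1"))
    if (!r$law$kind %in% .RATE_KINDS)
      return(paste0("reaction ", r$id, ": unknown rate law kind"))
    participating <- c(participating, refs)
  }
  orphans <- setdiff(ids, participating)
  if (length(orphans))
    return(paste("species participate in no reaction:",
                 paste(orphans, collapse = ", ")))
  if (!all(names(object@moduleLabels) == rids))
    return("moduleLabels must be named by reaction id, in order")
  if (any(!object@moduleLabels %in% .MODULES))
    return("unknown module label")
  TRUE
})

#' StimulusProtocol: ordered environment/ligand phases
#'
#' @slot phases list of phases; each phase has label, duration (h),
#'   environment (O2_fraction, glucose_mmol_L), ligand_doses (named
#'   numeric, molecules per cell added at phase start).
#' @slot preEquilibration hours of control-environment equilibration
#'   before the first phase.
#' @export
setClass("StimulusProtocol",
  representation(phases = "list", preEquilibration = "numeric"))

setValidity("StimulusProtocol", function(object) {
  if (length(object@phases) < 1) return("protocol needs >= 1 phase")
  if (object@preEquilibration < 0) return("preEquilibration must be >= 0")
  for (p in object@phases) {
    if (!is.finite(p$duration) || p$duration <= 0)
      return("phase durations must be finite and > 0")
    if (!all(names(p$environment) %in% c("O2_fraction", "glucose_mmol_L")))
      return("environment keys restricted to O2_fraction and glucose_mmol_L")
    if (!is.null(p$environment$O2_fraction) &&
        (p$environment$O2_fraction < 0 || p$environment$O2_fraction > 1))
      return("O2_fraction must lie in [0, 1]")
    if (!is.null(p$environment$glucose_mmol_L) && p$environment$glucose_mmol_L < 0)
      return("glucose must be >= 0")
  }
  TRUE
})

#' Trajectory: simulated time grid x species matrix
#'
#' @slot times strictly increasing sampling times (hours).
#' @slot amounts matrix time x species (colnames = species ids).
#' @slot phaseMarks data.frame(time, phase) of protocol phase boundaries.
#' @slot clampCount number of post-integration negative values clamped to 0.
#' @export
setClass("Trajectory",
  representation(times = "numeric", amounts = "matrix",
                 phaseMarks = "data.frame", clampCount = "integer"))

setValidity("Trajectory", function(object) {
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (nrow(object@amounts) != length(object@times))
    return("amounts rows must match times")
  if (is.null(colnames(object@amounts))) return("amounts must name species")
  TRUE
})

#' ScoreSeries: proliferation, damage and cell-function time courses
#'
#' Cell function (CF) = proliferation / damage elementwise; all three equal
#' 1 at the control baseline.
#'
#' @slot times hours.
#' @slot proliferation,damage,cellFunction positive numeric vectors.
#' @slot baseline named numeric, marker id -> control value used for
#'   normalization.
#' @export
setClass("ScoreSeries",
  representation(times = "numeric", proliferation = "numeric",
                 damage = "numeric", cellFunction = "numeric",
                 baseline = "numeric"))

setValidity("ScoreSeries", function(object) {
  n <- length(object@times)
  if (length(object@proliferation) != n || length(object@damage) != n ||
      length(object@cellFunction) != n)
    return("score vectors must match times")
  rel <- abs(object@cellFunction - object@proliferation / object@damage) /
    pmax(abs(object@cellFunction), 1e-300)
  if (any(rel > 1e-8))
    return("cellFunction must equal proliferation / damage")
  TRUE
})

#' PhenotypeGrid: log2 marker fold changes over OGD x reox conditions
#'
#' @slot markers ordered marker ids (12).
#' @slot ogdDurations,reoxDurations hours.
#' @slot values matrix marker x condition of log2 fold changes vs control;
#'   condition columns are named "ogd<h>_reox<h>".
#' @export
setClass("PhenotypeGrid",
  representation(markers = "character", ogdDurations = "numeric",
                 reoxDurations = "numeric", values = "matrix"))

setValidity("PhenotypeGrid", function(object) {
  if (nrow(object@values) != length(object@markers))
    return("one row per marker required")
  if (ncol(object@values) !=
      length(object@ogdDurations) * length(object@reoxDurations))
    return("condition count must equal |ogd| x |reox|")
  TRUE
})

#' LHSDesign: stratified parameter-multiplier sample
#'
#' @slot parameterIds ordered parameter ids.
#' @slot multipliers matrix samples x parameters.
#' @slot range numeric length 2 (low, high).
#' @slot seed integer seed used.
#' @export
setClass("LHSDesign",
  representation(parameterIds = "character", multipliers = "matrix",
                 range = "numeric", seed = "integer"))

setValidity("LHSDesign", function(object) {
  m <- object@multipliers
  if (ncol(m) != length(object@parameterIds))
    return("one column per parameter required")
  lo <- object@range[1]; hi <- object@range[2]
  if (any(m < lo - 1e-12) || any(m > hi + 1e-12))
    return("multipliers must lie within the sampling range")
  n <- nrow(m)
  breaks <- seq(lo, hi, length.out = n + 1)
  for (j in seq_len(ncol(m))) {
    s <- findInterval(m[, j], breaks, rightmost.closed = TRUE)
    if (!all(sort(s) == seq_len(n)))
      return("each column must place exactly one sample per stratum")
  }
  TRUE
})

#' SensitivityResult: PRCC matrix with p-values
#'
#' @slot parameterIds,outputIds dimensions of the PRCC matrix.
#' @slot prcc matrix parameters x outputs in [-1, 1].
#' @slot pValues,pAdjusted matrices of raw and Benjamini-Hochberg adjusted
#'   p-values.
#' @slot nSamples complete sample count used.
#' @export
setClass("SensitivityResult",
  representation(parameterIds = "character", outputIds = "character",
                 prcc = "matrix", pValues = "matrix", pAdjusted = "matrix",
                 nSamples = "integer"))

setValidity("SensitivityResult", function(object) {
  if (any(abs(object@prcc) > 1 + 1e-9)) return("|PRCC| must be <= 1")
  if (any(object@pValues < 0 | object@pValues > 1))
    return("p-values must lie in [0, 1]")
  TRUE
})

#' VirtualCohort: parameter-multiplier variants of the base model
#'
#' @slot cells list; each cell has cellId, multipliers (named numeric) and
#'   provenance (heterogeneity seed, intervention spec).
#' @slot metadata list.
#' @export
setClass("VirtualCohort",
  representation(cells = "list", metadata = "list"))

setValidity("VirtualCohort", function(object) {
  for (cell in object@cells) {
    if (any(cell$multipliers <= 0)) return("multipliers must be > 0")
    het <- cell$provenance$heterogeneity
    if (!is.null(het) && (any(het < 0.5 - 1e-9) || any(het > 2 + 1e-9)))
      return("heterogeneity multipliers must lie in [0.5, 2]")
  }
  TRUE
})

#' CohortResult: per-cell scores plus population summaries
#' @slot cells list of per-cell results (scores ScoreSeries, endpoint numeric).
#' @slot summary list of population summaries.
#' @slot failures character vector of failed cell ids.
#' @export
setClass("CohortResult",
  representation(cells = "list", summary = "list", failures = "character"))

#' CalibrationDataset: one observable's time course under one protocol
#'
#' @slot datasetId identifier.
#' @slot protocol StimulusProtocol the data were collected under.
#' @slot observable species id.
#' @slot timepoints hours from stimulus start.
#' @slot values nonnegative normalized values.
#' @slot normalization "to_max" or "to_baseline".
#' @slot weight positive weight in the objective.
#' @slot module pathway module label.
#' @slot provenance list (true parameters, noise, seed) for recovery tests.
#' @export
setClass("CalibrationDataset",
  representation(datasetId = "character", protocol = "StimulusProtocol",
                 observable = "character", timepoints = "numeric",
                 values = "numeric", normalization = "character",
                 weight = "numeric", module = "character",
                 provenance = "list"))

setValidity("CalibrationDataset", function(object) {
  if (length(object@timepoints) != length(object@values))
    return("timepoints and values must have equal length")
  if (length(object@values) < 2) return("need >= 2 points")
  if (any(object@values < 0)) return("values must be nonnegative")
  if (!object@normalization %in% c("to_max", "to_baseline"))
    return("normalization must be to_max or to_baseline")
  if (object@normalization == "to_max" && any(object@values > 1 + 1e-6))
    return("to_max values must be <= 1 + tolerance")
  if (object@weight <= 0) return("weight must be positive")
  TRUE
})

#' FitResult: outcome of a bounded pattern-search fit
#' @slot values fitted parameter values (named).
#' @slot objective final objective value.
#' @slot iterations poll iterations used.
#' @slot evaluations objective evaluations used.
#' @slot converged logical (mesh collapsed below tolerance).
#' @slot residuals list of per-dataset residual vectors.
#' @export
setClass("FitResult",
  representation(values = "numeric", objective = "numeric",
                 iterations = "integer", evaluations = "integer",
                 converged = "logical", residuals = "list"))
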