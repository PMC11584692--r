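#' @include sensitivity.R
NULL

#' Generate a heterogeneous virtual-cell cohort
#'
#' Each virtual cell is a parameter-multiplier variant of the base model:
#' the selected parameters receive i.i.d. multipliers drawn from a normal
#' distribution centered at 1 (sd \code{sd}), resampled into [0.5, 2].
#'
#' @param baseParams ParameterSet (used to validate ids).
#' @param variedParamIds parameters to vary (nonempty; default: the
#'   heterogeneity registry derived from the PRCC ranking of the
#'   cell-function output).
#' @param nCells number of cells (default 100).
#' @param seed integer seed.
#' @param sd standard deviation of the heterogeneity distribution.
#' @return a \code{VirtualCohort}.
#' @export
generateCohort <- function(baseParams,
                           variedParamIds = defaultHeterogeneityParams(),
                           nCells = 100, seed = 1L, sd = 0.25) {
  if (nCells < 1) stop("nCells must be >= 1")
  if (!length(variedParamIds)) stop("variedParamIds must be nonempty")
  unknown <- setdiff(variedParamIds, names(baseParams@values))
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
  cells <- withr::with_seed(as.integer(seed), lapply(seq_len(nCells),
    function(i) {
      m <- vapply(variedParamIds, function(p) {
        repeat {
          x <- stats::rnorm(1, 1, sd)
          if (x >= 0.5 && x <= 2) return(x)
        }
      }, numeric(1))
      list(cellId = sprintf("cell%03d", i), multipliers = m,
           provenance = list(heterogeneity = m,
                             heterogeneity_seed = as.integer(seed),
                             intervention = NULL))
    }))
  new("VirtualCohort", cells = cells,
      metadata = list(seed = as.integer(seed), sd = sd,
                      varied = variedParamIds))
}

#' Apply an in-silico target intervention to a cohort
#'
#' Each cell's grouped parameters receive an additional uniform
#' multiplier in [low, high], composed multiplicatively with the
#' heterogeneity multipliers, emulating variable intervention efficacy
#' (default 0.5x to 0.8x, i.e. inhibition). Mode "enhance" uses the
#' reciprocal range.
#'
#' @param cohort a VirtualCohort.
#' @param target one of "succinate", "p53", "HIF1a", "IkB" (see
#'   \code{\link{targetGroups}}).
#' @param low,high intervention multiplier range (inhibition: < 1).
#' @param seed integer seed for the per-cell efficacy draw.
#' @param mode "inhibit" or "enhance".
#' @return a new \code{VirtualCohort}.
#' @export
applyIntervention <- function(cohort, target, low = 0.5, high = 0.8,
                              seed = 1L, mode = c("inhibit", "enhance")) {
  mode <- match.arg(mode)
  groups <- targetGroups()
  if (!target %in% names(groups)) stop("unknown target: ", target)
  group <- groups[[target]]
  if (!length(group)) stop("empty parameter group for ", target)
  eff <- withr::with_seed(as.integer(seed),
                          stats::runif(length(cohort@cells), low, high))
  if (mode == "enhance") eff <- 1 / eff
  cells <- lapply(seq_along(cohort@cells), function(i) {
    cell <- cohort@cells[[i]]
    m <- cell$multipliers
    for (p in group) m[p] <- if (p %in% names(m)) m[p] * eff[i] else eff[i]
    # names() on an empty-augment case: ensure named
    if (is.null(names(m))) names(m) <- group
    cell$multipliers <- m
    cell$provenance$intervention <-
      list(target = target, low = low, high = high, mode = mode,
           seed = as.integer(seed), efficacy = eff[i])
    cell
  })
  new("VirtualCohort", cells = cells,
      metadata = c(cohort@metadata,
                   list(intervention = list(target = target, low = low,
                                            high = high, mode = mode,
                                            seed = as.integer(seed)))))
}

#' Simulate a virtual cohort under a stimulus protocol
#'
#' Each cell's parameters are the base parameters scaled by its
#' multipliers. Normalization baselines come from each cell's OWN control
#' equilibration (so heterogeneity does not masquerade as dysfunction):
#' the cell is first relaxed under control conditions, and that state
#' seeds the protocol and provides the baseline marker values. Failures
#' are logged per cell and excluded; more than \code{maxFailFraction}
#' failures aborts.
#'
#' @param network a ReactionNetwork.
#' @param baseParams ParameterSet.
#' @param cohort a VirtualCohort.
#' @param protocol a StimulusProtocol (default OGD 6 h / R 24 h with 72 h
#'   pre-equilibration to absorb the parameter-induced baseline shift).
#' @param state common starting state for the control relaxation.
#' @param settings integration settings.
#' @param maxFailFraction failure tolerance (default 0.1).
#' @return a \code{CohortResult}; each cell record holds its ScoreSeries
#'   and endpoint scores.
#' @export
simulateCohort <- function(network, baseParams, cohort,
                           protocol = makeOGDRProtocol(6, 24,
                                                       preEquilibration = 72),
                           state = initialState(network),
                           settings = simSettings(),
                           maxFailFraction = 0.1) {
  cells <- list()
  failures <- character(0)
  for (cell in cohort@cells) {
    res <- tryCatch({
      p <- scaleParameters(baseParams, cell$multipliers)
      # pre-equilibrate with the cell's intrinsic (heterogeneity-only)
      # parameters; interventions act acutely from stimulus onset
      het <- cell$provenance$heterogeneity
      pHet <- if (!is.null(het)) scaleParameters(baseParams, het) else p
      traj <- runProtocol(network, p, state, protocol, settings,
                          preEqParams = pHet)
      score <- cellFunctionScore(traj)
      list(cellId = cell$cellId, score = score,
           endpoint = c(proliferation = score@proliferation[length(score@times)],
                        damage = score@damage[length(score@times)],
                        cell_function = endpointCF(score)))
    }, error = function(e) NULL)
    if (is.null(res)) failures <- c(failures, cell$cellId)
    else cells[[res$cellId]] <- res
  }
  if (length(failures) / length(cohort@cells) > maxFailFraction)
    stop("cohort error: ", length(failures), "/", length(cohort@cells),
         " cells failed")
  cf <- vapply(cells, function(x) x$endpoint["cell_function"], numeric(1))
  summ <- list(n = length(cells), failed = length(failures),
               median_cf = stats::median(cf),
               iqr_cf = unname(stats::quantile(cf, c(0.25, 0.75))))
  new("CohortResult", cells = cells, summary = summ, failures = failures)
}

#' Single-cell target modulation experiment
#'
#' Runs a matched treated/control pair on the standard (non-heterogeneous)
#' cell: the treated run scales the target's parameter group by
#' \code{strength}; both runs share the protocol, and each is normalized
#' to its own control baseline.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet.
#' @param target one of "succinate", "p53", "HIF1a", "IkB".
#' @param strength multiplier in (0, 1] applied to the target group.
#' @param protocol a StimulusProtocol (default OGD 6 h / R 24 h with 72 h
#'   pre-equilibration).
#' @param state starting state.
#' @param settings integration settings.
#' @return list(treated, control) of \code{ScoreSeries}.
#' @export
simulateTargetModulation <- function(network,
                                     params = defaultParameters(network),
                                     target, strength,
                                     protocol = makeOGDRProtocol(6, 24,
                                       preEquilibration = 72),
                                     state = initialState(network),
                                     settings = simSettings()) {
  groups <- targetGroups()
  if (!target %in% names(groups)) stop("unknown target: ", target)
  if (strength <= 0 || strength > 1) stop("strength must be in (0, 1]")
  mult <- stats::setNames(rep(strength, length(groups[[target]])),
                          groups[[target]])
  pTreat <- scaleParameters(params, mult)
  trC <- runProtocol(network, params, state, protocol, settings)
  # acute modulation: shared control pre-equilibration, treated parameters
  # from stimulus onset
  trT <- runProtocol(network, pTreat, state, protocol, settings,
                     preEqParams = params)
  list(treated = cellFunctionScore(trT), control = cellFunctionScore(trC))
}

#' Summarize a paired cohort experiment
#'
#' Computes per-cell endpoint cell-function fold changes
#' (treated/control) over cells shared by both results, with the median,
#' quartiles, histogram data and the fraction of cells improved
#' (fold change strictly > 1).
#'
#' @param treated,control \code{CohortResult}s sharing cell ids.
#' @param breaks histogram breaks passed to \code{hist}.
#' @return list(fold_changes, median, quartiles, fraction_improved,
#'   histogram, boxplot_stats).
#' @export
summarizeCohort <- function(treated, control, breaks = "Sturges") {
  idsT <- names(treated@cells)
  idsC <- names(control@cells)
  shared <- intersect(idsT, idsC)
  if (!length(shared)) stop("id mismatch: no shared cells")
  fc <- vapply(shared, function(id)
    treated@cells[[id]]$endpoint["cell_function"] /
      control@cells[[id]]$endpoint["cell_function"], numeric(1))
  names(fc) <- shared
  h <- graphics::hist(fc, breaks = breaks, plot = FALSE)
  list(fold_changes = fc,
       median = stats::median(fc),
       quartiles = stats::quantile(fc, c(0.25, 0.5, 0.75)),
       fraction_improved = mean(fc > 1),
       histogram = list(breaks = h$breaks, counts = h$counts),
       boxplot_stats = grDevices::boxplot.stats(fc)$stats)
}

#' Write per-cell cohort results as CSV
#' @param result a CohortResult.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCohortCSV <- function(result, file) {
  df <- do.call(rbind, lapply(result@cells, function(x)
    data.frame(cell = x$cellId,
               proliferation = x$endpoint["proliferation"],
               damage = x$endpoint["damage"],
               cell_function = x$endpoint["cell_function"],
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
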