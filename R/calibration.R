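#' @include cohort.R
NULL

#' Normalize a simulated observable for comparison with data
#'
#' "to_max" divides the series by its maximum over the stimulus window;
#' "to_baseline" divides by the pre-stimulus (t = 0) value.
#'
#' @param traj a Trajectory from \code{\link{runProtocol}}.
#' @param observable species id.
#' @param normalization "to_max" or "to_baseline".
#' @return list(times, values) over the stimulus window (t >= 0).
#' @export
normalizeObservable <- function(traj, observable,
                                normalization = c("to_max", "to_baseline")) {
  normalization <- match.arg(normalization)
  y <- speciesSeries(traj, observable)
  sel <- traj@times >= 0
  tt <- traj@times[sel]
  yy <- y[sel]
  ref <- if (normalization == "to_max") max(yy) else yy[1]
  if (!is.finite(ref) || ref <= 0)
    stop("normalization error: nonpositive ", normalization,
         " reference for ", observable)
  list(times = tt, values = yy / ref)
}

.protocolKey <- function(protocol) {
  paste(vapply(protocol@phases, function(p)
    paste(p$label, p$duration,
          p$environment$O2_fraction, p$environment$glucose_mmol_L,
          paste(names(p$ligand_doses), signif(p$ligand_doses, 8),
                collapse = "+"), sep = "|"), character(1)),
    collapse = ";")
}

#' Weighted least-squares calibration objective
#'
#' Simulates each distinct protocol once, interpolates the normalized
#' observable onto the dataset timepoints, and returns the weighted sum
#' of squared residuals over all datasets. A failed simulation
#' contributes a large finite penalty and is logged.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet or named numeric values.
#' @param datasets list of \code{CalibrationDataset}.
#' @param state quiescent starting state.
#' @param settings integration settings.
#' @param penalty objective value charged per failed protocol simulation.
#' @return scalar objective (>= 0) with attribute "residuals" (list per
#'   dataset id).
#' @export
calibrationObjective <- function(network, params, datasets,
                                 state = initialState(network),
                                 settings = simSettings(),
                                 penalty = 1e6) {
  if (!length(datasets)) stop("datasets must be nonempty")
  pv <- if (is(params, "ParameterSet")) params else
    updateParameters(defaultParameters(network), params)
  keys <- vapply(datasets, function(d) .protocolKey(d@protocol), character(1))
  total <- 0
  residuals <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    proto <- datasets[[idx[1]]]@protocol
    traj <- tryCatch(
      runProtocol(network, pv, state, proto, settings),
      error = function(e) NULL)
    for (i in idx) {
      d <- datasets[[i]]
      if (is.null(traj)) {
        total <- total + penalty
        residuals[[d@datasetId]] <- rep(NA_real_, length(d@values))
        next
      }
      sim <- normalizeObservable(traj, d@observable, d@normalization)
      yhat <- stats::approx(sim$times, sim$values, xout = d@timepoints,
                            rule = 2)$y
      r <- yhat - d@values
      residuals[[d@datasetId]] <- r
      total <- total + d@weight * sum(r^2)
    }
  }
  structure(total, residuals = residuals)
}

#' Bounded pattern-search parameter fit
#'
#' Generalized pattern search in log-parameter space: polls the
#' +/- coordinate directions around the incumbent, accepts the best
#' improving point, expands the mesh on success and contracts it on
#' failure, and projects onto the (log-transformed) box bounds. The
#' search is deterministic given the seed (used only to shuffle the
#' polling order) and never returns a point worse than the start.
#'
#' @param network a ReactionNetwork.
#' @param params0 starting ParameterSet (values within bounds).
#' @param freeParamIds parameters to fit; all others stay fixed.
#' @param datasets list of CalibrationDataset.
#' @param maxIterations maximum objective evaluations (default 10000).
#' @param seed integer seed.
#' @param meshInit initial mesh size in log2 units.
#' @param meshTol mesh size below which the search is declared converged.
#' @param state,settings forwarded to the objective.
#' @return a \code{FitResult}.
#' @export
patternSearchFit <- function(network, params0, freeParamIds, datasets,
                             maxIterations = 10000, seed = 1L,
                             meshInit = 0.5, meshTol = 1e-3,
                             state = initialState(network),
                             settings = simSettings()) {
  if (maxIterations < 1) stop("maxIterations must be >= 1")
  unknown <- setdiff(freeParamIds, names(params0@values))
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
  b <- params0@bounds[freeParamIds, , drop = FALSE]
  lo <- log2(b[, "low"]); hi <- log2(b[, "high"])
  x <- pmin(pmax(log2(params0@values[freeParamIds]), lo), hi)
  evalAt <- function(xx) {
    p <- updateParameters(params0,
                          stats::setNames(2^xx, freeParamIds))
    as.numeric(calibrationObjective(network, p, datasets, state, settings))
  }
  fbest <- evalAt(x)
  evals <- 1L
  iter <- 0L
  mesh <- meshInit
  k <- length(x)
  dirs <- rbind(diag(k), -diag(k))
  converged <- FALSE
  rng <- withr::with_seed(as.integer(seed),
                          sample.int(nrow(dirs)))  # fixed polling order
  dirs <- dirs[rng, , drop = FALSE]
  while (evals < maxIterations) {
    iter <- iter + 1L
    fpoll <- rep(Inf, nrow(dirs))
    xs <- vector("list", nrow(dirs))
    for (d in seq_len(nrow(dirs))) {
      if (evals >= maxIterations) break
      xd <- pmin(pmax(x + mesh * dirs[d, ], lo), hi)
      if (all(xd == x)) next
      fpoll[d] <- evalAt(xd)
      xs[[d]] <- xd
      evals <- evals + 1L
    }
    best <- which.min(fpoll)
    if (length(best) && is.finite(fpoll[best]) && fpoll[best] < fbest) {
      x <- xs[[best]]
      fbest <- fpoll[best]
      mesh <- min(mesh * 2, meshInit)
    } else {
      mesh <- mesh / 2
      if (mesh < meshTol) { converged <- TRUE; break }
    }
  }
  final <- updateParameters(params0, stats::setNames(2^x, freeParamIds))
  obj <- calibrationObjective(network, final, datasets, state, settings)
  new("FitResult", values = final@values, objective = as.numeric(obj),
      iterations = iter, evaluations = evals, converged = converged,
      residuals = attr(obj, "residuals"))
}

#' Per-parameter recovery errors of a fit
#'
#' Relative errors |fitted - true| / true for the free parameters, with
#' median and maximum.
#'
#' @param trueParams ParameterSet (or named numeric) of true values.
#' @param fit a FitResult.
#' @param freeParamIds the fitted parameter ids.
#' @return list(errors, median, max).
#' @export
evaluateRecovery <- function(trueParams, fit, freeParamIds) {
  tv <- if (is(trueParams, "ParameterSet")) trueParams@values else trueParams
  err <- abs(fit@values[freeParamIds] - tv[freeParamIds]) / tv[freeParamIds]
  list(errors = err, median = stats::median(err), max = max(err))
}

#' Module-by-module calibration followed by global refinement
#'
#' Mirrors the two-stage procedure: each pathway module is first fitted
#' against only its own datasets and parameters, then a global refinement
#' fits all free parameters against all datasets simultaneously.
#'
#' @param network a ReactionNetwork.
#' @param params0 starting ParameterSet.
#' @param freeParamIds named list module -> parameter ids (stage 1) or a
#'   plain character vector (all assigned to stage 2).
#' @param datasets list of CalibrationDataset (their \code{module} slots
#'   route stage 1).
#' @param iterationsPerStage objective evaluation budget per stage.
#' @param seed integer seed.
#' @param ... forwarded to \code{\link{patternSearchFit}}.
#' @return a \code{FitResult} from the global stage.
#' @export
stagedCalibration <- function(network, params0, freeParamIds, datasets,
                              iterationsPerStage = 500, seed = 1L, ...) {
  cur <- params0
  allFree <- unlist(freeParamIds, use.names = FALSE)
  if (is.list(freeParamIds)) {
    for (mod in names(freeParamIds)) {
      sub <- Filter(function(d) identical(d@module, mod), datasets)
      if (!length(sub)) next
      fit <- patternSearchFit(network, cur, freeParamIds[[mod]], sub,
                              maxIterations = iterationsPerStage,
                              seed = seed, ...)
      cur <- updateParameters(cur, fit@values[freeParamIds[[mod]]])
    }
  }
  patternSearchFit(network, cur, allFree, datasets,
                   maxIterations = iterationsPerStage, seed = seed, ...)
}

#' Read calibration datasets from tidy CSV
#'
#' Expects columns dataset_id, time_h, value, observable, protocol_ref,
#' normalization, weight. \code{protocol_ref} strings of the form
#' "ogdr:OGD/REOX", "hypoxia:O2/HOURS" or "control:HOURS" are expanded to
#' protocols.
#'
#' @param file CSV path.
#' @return list of CalibrationDataset.
#' @export
readCalibrationCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(df, df$dataset_id), function(d) {
    ref <- strsplit(d$protocol_ref[1], ":", fixed = TRUE)[[1]]
    num2 <- function(x) as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
    proto <- switch(ref[1],
      ogdr = { v <- num2(ref[2]); makeOGDRProtocol(v[1], v[2]) },
      hypoxia = { v <- num2(ref[2]); hypoxiaProtocol(v[1], v[2]) },
      control = controlProtocol(as.numeric(ref[2])),
      stimulus = {
        kv <- strsplit(strsplit(ref[2], "+", fixed = TRUE)[[1]], "=",
                       fixed = TRUE)
        doses <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                        numeric(1)),
                                 vapply(kv, `[[`, character(1), 1))
        ligandProtocol(doses, as.numeric(ref[3]))
      },
      stop("unknown protocol_ref: ", d$protocol_ref[1]))
    new("CalibrationDataset", datasetId = d$dataset_id[1], protocol = proto,
        observable = d$observable[1], timepoints = d$time_h,
        values = d$value, normalization = d$normalization[1],
        weight = d$weight[1],
        module = if ("module" %in% names(d)) d$module[1] else NA_character_,
        provenance = list())
  })
}

#' Write calibration datasets as tidy CSV
#' @param datasets list of CalibrationDataset.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCalibrationCSV <- function(datasets, file) {
  rows <- do.call(rbind, lapply(datasets, function(d) {
    ref <- .protocolRef(d@protocol)
    data.frame(dataset_id = d@datasetId, time_h = d@timepoints,
               value = d@values, observable = d@observable,
               protocol_ref = ref, normalization = d@normalization,
               weight = d@weight, module = d@module,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

.protocolRef <- function(protocol) {
  ph <- protocol@phases
  labs <- vapply(ph, `[[`, character(1), "label")
  if (identical(labs, c("OGD", "reoxygenation")))
    sprintf("ogdr:%g/%g", ph[[1]]$duration, ph[[2]]$duration)
  else if (identical(labs, "hypoxia"))
    sprintf("hypoxia:%g/%g", ph[[1]]$environment$O2_fraction,
            ph[[1]]$duration)
  else if (identical(labs, "stimulus"))
    sprintf("stimulus:%s:%g",
            paste(names(ph[[1]]$ligand_doses),
                  signif(ph[[1]]$ligand_doses, 6),
                  sep = "=", collapse = "+"), ph[[1]]$duration)
  else sprintf("control:%g", protocolDuration(protocol))
}
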