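#' @include calibration.R
NULL

#' Multiplicative lognormal noise model
#'
#' Emulates the roughly constant coefficient of variation of
#' densitometry/ELISA relative measurements. sigma = 0 reproduces the
#' noiseless values exactly. Additive Gaussian noise is available as an
#' option.
#'
#' @param sigma log-scale standard deviation (>= 0).
#' @param kind "multiplicative_lognormal" or "additive_gaussian".
#' @return noise model list.
#' @export
noiseModel <- function(sigma = 0.05,
                       kind = c("multiplicative_lognormal",
                                "additive_gaussian")) {
  stopifnot(sigma >= 0)
  list(kind = match.arg(kind), sigma = sigma)
}

.applyNoise <- function(values, noise) {
  if (noise$sigma == 0) return(values)
  if (noise$kind == "multiplicative_lognormal")
    values * exp(stats::rnorm(length(values), 0, noise$sigma))
  else pmax(values + stats::rnorm(length(values), 0, noise$sigma), 0)
}

#' Generate one synthetic calibration time course
#'
#' Simulates the model with the given (true) parameters under the
#' protocol, samples the normalized observable at the requested
#' timepoints, applies measurement noise and re-normalizes (so to_max
#' data keep max 1). The true parameters are recorded in the dataset
#' provenance for recovery tests.
#'
#' @param network a ReactionNetwork.
#' @param trueParams ParameterSet.
#' @param protocol a StimulusProtocol.
#' @param observable species id.
#' @param timepoints hours from stimulus start (within the protocol).
#' @param noise a \code{\link{noiseModel}}.
#' @param normalization "to_max" or "to_baseline".
#' @param seed integer seed.
#' @param datasetId identifier.
#' @param module pathway module label recorded in metadata.
#' @param weight objective weight.
#' @param state,settings forwarded to the simulation.
#' @return a \code{CalibrationDataset}.
#' @export
generateTimecourseDataset <- function(network, trueParams, protocol,
                                      observable, timepoints,
                                      noise = noiseModel(0),
                                      normalization = "to_max", seed = 1L,
                                      datasetId = observable,
                                      module = "inflammation", weight = 1,
                                      state = initialState(network),
                                      settings = simSettings()) {
  if (any(timepoints < 0) || any(timepoints > protocolDuration(protocol)))
    stop("timepoints must lie within the protocol duration")
  traj <- runProtocol(network, trueParams, state, protocol, settings)
  sim <- normalizeObservable(traj, observable, normalization)
  y <- stats::approx(sim$times, sim$values, xout = timepoints, rule = 2)$y
  y <- withr::with_seed(as.integer(seed), .applyNoise(y, noise))
  # keep the full-trajectory max as the normalization reference; only
  # rescale when noise pushes samples above 1
  if (normalization == "to_max") y <- y / max(1, max(y))
  new("CalibrationDataset", datasetId = datasetId, protocol = protocol,
      observable = observable, timepoints = timepoints, values = y,
      normalization = normalization, weight = weight, module = module,
      provenance = list(true_params = trueParams@values, noise = noise,
                        seed = as.integer(seed)))
}

#' Default synthetic calibration corpus specification
#'
#' Stimulation conditions mirroring the calibration corpus structure:
#' TNFa 100 ng/ml, LPS 300 ng/ml, VEGF 50 ng/ml, FGF 1 ug/ml boluses,
#' 1\% O2 hypoxia, and OGD 6 h / reoxygenation 24 h, each observed through
#' the pathway readouts it drives.
#'
#' @return list of condition specs (protocol, observables, timepoints,
#'   module labels).
#' @export
defaultCalibrationSpec <- function() {
  density <- 1e6
  list(
    list(name = "tnfa",
         protocol = ligandProtocol(c(TNFa = convertDose(100, 17500, density)), 6),
         timepoints = seq(0.25, 6, length.out = 9),
         observables = c(RIPK1_Ub = "inflammation", TAK1p = "inflammation",
                         IKKp = "inflammation", NFkB_nuc = "inflammation",
                         IL6 = "inflammation")),
    list(name = "lps",
         protocol = ligandProtocol(c(LPS = convertDose(300, 1e5, density)), 6),
         timepoints = seq(0.25, 6, length.out = 9),
         observables = c(TRAF6_Ub = "inflammation", p38p = "inflammation",
                         JNKp = "inflammation", ERKp = "inflammation")),
    list(name = "vegf",
         protocol = ligandProtocol(c(VEGF = convertDose(50, 4e4, density)), 4),
         timepoints = seq(0.1, 4, length.out = 8),
         observables = c(VEGFR_pY1175 = "survival", VEGFR_pY951 = "survival",
                         PLCgp = "survival", MEKp = "survival",
                         ERKp = "survival", PI3Kp = "survival",
                         AKTp = "survival", Ca_cyt = "survival",
                         eNOSp = "survival")),
    list(name = "fgf",
         protocol = ligandProtocol(c(FGF = convertDose(1000, 17500, density)), 4),
         timepoints = seq(0.1, 4, length.out = 8),
         observables = c(FGFRp = "survival", PKCp = "survival",
                         AKTp = "survival")),
    list(name = "hypoxia1pct",
         protocol = hypoxiaProtocol(0.01, 12),
         timepoints = seq(0.5, 12, length.out = 8),
         observables = c(HIF1a = "hypoxia", HIF2a = "hypoxia",
                         Lon = "hypoxia", BDNF = "hypoxia",
                         SEMA3G = "hypoxia", Ang2 = "hypoxia",
                         p53 = "hypoxia", MDM2 = "hypoxia",
                         TIGAR = "metabolism", NADPH = "metabolism",
                         PFKFB3 = "metabolism")),
    list(name = "ogdr",
         protocol = makeOGDRProtocol(6, 24),
         timepoints = c(1, 2, 4, 6, 6.5, 7, 8, 10, 14, 18, 24, 30),
         observables = c(Succinate = "oxidative_stress",
                         ROS = "oxidative_stress", ATP = "metabolism",
                         AMPKp = "metabolism", iNOS = "oxidative_stress",
                         NO = "oxidative_stress", ONOO = "oxidative_stress",
                         BH4 = "oxidative_stress", BH2 = "oxidative_stress",
                         NRF2act = "oxidative_stress",
                         ZO1 = "oxidative_stress",
                         Claudin5 = "oxidative_stress",
                         p53 = "survival", Casp3 = "survival")))
}

#' Generate the default synthetic calibration suite
#'
#' Builds one dataset per (condition, observable) pair of the
#' specification, covering all five pathway modules with more than 300
#' data points in total.
#'
#' @param network a ReactionNetwork.
#' @param trueParams ParameterSet used as ground truth.
#' @param spec condition list (default \code{\link{defaultCalibrationSpec}}).
#' @param noise a \code{\link{noiseModel}}.
#' @param seed integer seed (one stream per dataset, derived).
#' @param state,settings forwarded to the simulations.
#' @return list of \code{CalibrationDataset}.
#' @export
generateCalibrationSuite <- function(network, trueParams,
                                     spec = defaultCalibrationSpec(),
                                     noise = noiseModel(0), seed = 1L,
                                     state = initialState(network),
                                     settings = simSettings()) {
  if (!length(spec)) stop("spec must be nonempty")
  datasets <- list()
  counter <- 0L
  for (cond in spec) {
    traj <- runProtocol(network, trueParams, state, cond$protocol, settings)
    for (obs in names(cond$observables)) {
      counter <- counter + 1L
      sim <- normalizeObservable(traj, obs, "to_max")
      y <- stats::approx(sim$times, sim$values, xout = cond$timepoints,
                         rule = 2)$y
      y <- withr::with_seed(as.integer(seed) + counter,
                            .applyNoise(y, noise))
      y <- y / max(1, max(y))
      id <- paste(cond$name, obs, sep = "_")
      datasets[[id]] <- new("CalibrationDataset", datasetId = id,
        protocol = cond$protocol, observable = obs,
        timepoints = cond$timepoints, values = y,
        normalization = "to_max", weight = 1,
        module = unname(cond$observables[obs]),
        provenance = list(true_params = trueParams@values, noise = noise,
                          seed = as.integer(seed) + counter))
    }
  }
  datasets
}

#' Total data points in a calibration suite
#' @param datasets list of CalibrationDataset.
#' @return integer count.
#' @export
suitePoints <- function(datasets) {
  sum(vapply(datasets, function(d) length(d@values), integer(1)))
}
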