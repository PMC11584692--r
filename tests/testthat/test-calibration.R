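constDataset <- function(values, timepoints = c(1, 2), weight = 1,
                         normalization = "to_baseline") {
  new("CalibrationDataset", datasetId = "toy", protocol = controlProtocol(4),
      observable = "P", timepoints = timepoints, values = values,
      normalization = normalization, weight = weight, module = "metabolism",
      provenance = list())
}

test_that("observable normalization matches its definitions", {
  tt <- c(0, 1, 2)
  m <- matrix(c(1, 2, 4), 3, 1, dimnames = list(NULL, "A"))
  tr <- new("Trajectory", times = tt, amounts = m,
            phaseMarks = data.frame(time = 0, phase = "stimulus"),
            clampCount = 0L)
  expect_equal(normalizeObservable(tr, "A", "to_max")$values,
               c(0.25, 0.5, 1))
  expect_equal(normalizeObservable(tr, "A", "to_baseline")$values,
               c(1, 2, 4))
  const <- tr; const@amounts[] <- 3
  expect_equal(normalizeObservable(const, "A", "to_baseline")$values,
               rep(1, 3))
  # peak equals exactly 1 at the peak time under to_max
  peak <- normalizeObservable(tr, "A", "to_max")
  expect_equal(max(peak$values), 1)
  zero <- tr; zero@amounts[] <- 0
  expect_error(normalizeObservable(zero, "A", "to_max"), "normalization")
})

test_that("objective is a weighted sum of squared residuals", {
  # steady toy model: normalized P is identically 1 under control
  net <- toyPairNetwork()
  p <- defaultParameters(net)
  d <- constDataset(c(0.9, 1.2))  # residuals 0.1 and -0.2
  expect_equal(as.numeric(calibrationObjective(net, p, d = list(d))), 0.05,
               tolerance = 1e-9)
  d2 <- constDataset(c(0.9, 1.2), weight = 2)
  expect_equal(as.numeric(calibrationObjective(net, p, d = list(d2))), 0.1,
               tolerance = 1e-9)
  # self-consistency: data generated by the model itself give ~0
  exact <- constDataset(c(1, 1))
  expect_lt(as.numeric(calibrationObjective(net, p, d = list(exact))),
            1e-12)
})

test_that("pattern search recovers a 1-parameter optimum and never regresses", {
  # fit the decay rate of a single-species model to noiseless data
  net <- toyDecayNetwork(kd = 0.4, A0 = 1)
  true <- defaultParameters(net)
  proto <- stimulusProtocol(protocolPhase("obs", 6), preEquilibration = 0)
  ds <- generateTimecourseDataset(net, true, proto, "A",
                                  timepoints = seq(0.5, 6, 0.5),
                                  normalization = "to_baseline")
  start <- updateParameters(true, c(kd_A = 0.4 * 1.6))
  f0 <- as.numeric(calibrationObjective(net, start, list(ds)))
  fit <- patternSearchFit(net, start, "kd_A", list(ds),
                          maxIterations = 120, seed = 1)
  expect_lte(fit@objective, f0)
  expect_true(fit@converged)
  expect_equal(unname(fit@values["kd_A"]), 0.4, tolerance = 1e-3)
  # bounds are respected
  expect_gte(fit@values["kd_A"], parameterBounds(start)["kd_A", "low"])
  expect_lte(fit@values["kd_A"], parameterBounds(start)["kd_A", "high"])
})

test_that("a flat objective returns the start after mesh collapse", {
  net <- toyPairNetwork()
  p <- defaultParameters(net)
  # the dataset equals the simulation regardless of kd_P scaling within
  # bounds? no - use a parameter with no effect on the observable:
  b <- networkBuilder()
  addSpecies(b, "P", "cytosol", 1, "relative")
  addSpecies(b, "Q", "cytosol", 1, "relative")
  addReaction(b, "kt_P", "metabolism", products = c(P = 1),
              law = rateLaw("zeroth_order_synthesis", "kt_P"), k = 1)
  addReaction(b, "kd_P", "metabolism", reactants = c(P = 1),
              law = rateLaw("first_order_decay", "kd_P"), k = 1)
  addReaction(b, "kd_Q", "metabolism", reactants = c(Q = 1),
              law = rateLaw("first_order_decay", "kd_Q"), k = 0.3)
  net2 <- finalizeNetwork(b, balance = FALSE)
  p2 <- defaultParameters(net2)
  ds <- constDataset(c(1, 1))
  fit <- patternSearchFit(net2, p2, "kd_Q", list(ds),
                          maxIterations = 200, seed = 1)
  expect_true(fit@converged)
  expect_equal(unname(fit@values["kd_Q"]), 0.3, tolerance = 1e-12)
})

test_that("recovery evaluation reports relative errors", {
  true <- c(a = 2, b = 10)
  fit <- new("FitResult", values = c(a = 2, b = 20), objective = 0,
             iterations = 0L, evaluations = 0L, converged = TRUE,
             residuals = list())
  r <- evaluateRecovery(true, fit, c("a", "b"))
  expect_equal(unname(r$errors), c(0, 1))
  expect_equal(r$median, 0.5)
  expect_equal(r$max, 1)
  fit2 <- fit; fit2@values <- true
  expect_equal(evaluateRecovery(true, fit2, c("a", "b"))$max, 0)
})

test_that("calibration CSV round trip preserves datasets", {
  m <- defaultModel()
  ds <- list(
    generateTimecourseDataset(m$network, m$params, makeOGDRProtocol(2, 2),
                              "Succinate", c(0.5, 1, 2, 3),
                              datasetId = "succ",
                              module = "oxidative_stress",
                              state = m$state),
    generateTimecourseDataset(m$network, m$params,
                              ligandProtocol(c(TNFa = 1e5), 2), "IKKp",
                              c(0.25, 0.5, 1, 2), datasetId = "ikk",
                              module = "inflammation", state = m$state))
  f <- tempfile(fileext = ".csv")
  writeCalibrationCSV(ds, f)
  back <- readCalibrationCSV(f)
  expect_setequal(names(back), c("succ", "ikk"))
  for (id in names(back)) {
    orig <- ds[[which(vapply(ds, function(d) d@datasetId, "") == id)]]
    expect_equal(back[[id]]@values, orig@values, tolerance = 1e-6)
    expect_equal(back[[id]]@timepoints, orig@timepoints)
    expect_identical(back[[id]]@observable, orig@observable)
    expect_equal(protocolDuration(back[[id]]@protocol),
                 protocolDuration(orig@protocol))
  }
})
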