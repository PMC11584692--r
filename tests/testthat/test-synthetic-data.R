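test_that("noiseless datasets reproduce the normalized simulation exactly", {
  net <- toyPairNetwork()
  p <- defaultParameters(net)
  proto <- controlProtocol(4, preEquilibration = 0)
  ds <- generateTimecourseDataset(net, p, proto, "P", c(1, 2, 3),
                                  noise = noiseModel(0))
  expect_equal(ds@values, rep(1, 3))  # steady state normalized to max
  ds2 <- generateTimecourseDataset(net, p, proto, "P", c(1, 2, 3),
                                   noise = noiseModel(0.1), seed = 9)
  ds3 <- generateTimecourseDataset(net, p, proto, "P", c(1, 2, 3),
                                   noise = noiseModel(0.1), seed = 9)
  expect_identical(ds2@values, ds3@values)
  expect_false(identical(ds@values, ds2@values))
  expect_error(generateTimecourseDataset(net, p, proto, "P", c(1, 99)),
               "within the protocol")
})

test_that("multiplicative noise has the declared log-scale dispersion", {
  net <- toyPairNetwork()
  p <- defaultParameters(net)
  proto <- controlProtocol(4, preEquilibration = 0)
  # 1000 replicate draws at one timepoint
  ds <- generateTimecourseDataset(net, p, proto, "P", rep(2, 1000),
                                  noise = noiseModel(0.05),
                                  normalization = "to_baseline", seed = 17)
  expect_lt(abs(stats::sd(log(ds@values)) - 0.05), 0.005)
  expect_equal(mean(log(ds@values)), 0, tolerance = 0.01)
})

test_that("the default calibration suite covers the corpus structure", {
  m <- defaultModel()
  suite <- generateCalibrationSuite(m$network, m$params, state = m$state)
  expect_gte(suitePoints(suite), 300)
  mods <- vapply(suite, function(d) d@module, character(1))
  for (mod in c("inflammation", "survival", "hypoxia", "metabolism",
                "oxidative_stress"))
    expect_gte(sum(mods == mod), 3)
  # a one-dataset spec yields exactly its points
  spec1 <- list(list(name = "one", protocol = controlProtocol(4),
                     timepoints = 1:5,
                     observables = c(ATP = "metabolism")))
  small <- generateCalibrationSuite(m$network, m$params, spec = spec1,
                                    state = m$state)
  expect_equal(suitePoints(small), 5)
  expect_error(generateCalibrationSuite(m$network, m$params,
                                        spec = list()), "nonempty")
})

test_that("noiseless suite has zero objective at the true parameters", {
  m <- defaultModel()
  suite <- generateCalibrationSuite(m$network, m$params,
                                    noise = noiseModel(0), seed = 3,
                                    state = m$state)
  expect_lt(as.numeric(calibrationObjective(m$network, m$params, suite,
                                            state = m$state)), 1e-8)
})

test_that("shape fixtures are nonempty and machine-checkable", {
  fx <- defaultShapeFixtures()
  expect_gt(length(fx), 8)
  # every fixture evaluates to a boolean verdict on arbitrary trajectories
  protos <- names(fixtureProtocols())
  vals <- stats::setNames(c(rep(1000, 10), 1, 1, 1), c(
    "Succinate", "ROS", "AMPKp", "p53", "HIF1a", "IL6", "Ang2", "Casp3",
    "ZO1", "Claudin5", "a", "b", "c"))
  const <- syntheticTrajectory(vals, times = seq(0, 30, 0.5))
  trajs <- stats::setNames(rep(list(const), length(protos)), protos)
  for (id in names(fx)) {
    r <- evaluateFixture(fx[[id]], trajs)
    expect_type(r$pass, "logical")
  }
  # a constant trajectory cannot show the pAMPK double peak
  expect_false(evaluateFixture(fx$ampk_double_peak, trajs)$pass)
  expect_false(evaluateFixture(fx$ros_reox_peak, trajs)$pass)
})

test_that("sigma = 0 suites support exact round-trip recovery start", {
  # calibrating from the true parameters against a noiseless suite keeps
  # the objective at its floor (no spurious improvement directions)
  net <- toyDecayNetwork(kd = 0.3, A0 = 1)
  p <- defaultParameters(net)
  proto <- stimulusProtocol(protocolPhase("obs", 5), preEquilibration = 0)
  ds <- generateTimecourseDataset(net, p, proto, "A", seq(0.5, 5, 0.5),
                                  normalization = "to_baseline")
  fit <- patternSearchFit(net, p, "kd_A", list(ds), maxIterations = 60,
                          seed = 2)
  expect_lt(fit@objective, 1e-10)
  expect_equal(unname(fit@values["kd_A"]), 0.3, tolerance = 1e-6)
})
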