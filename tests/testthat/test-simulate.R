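test_that("exponential decay matches the closed form", {
  net <- toyDecayNetwork(kd = log(2), A0 = 100)
  tr <- simulateModel(net, defaultParameters(net), tEnd = 1)
  final <- unname(tr@amounts[nrow(tr@amounts), "A"])
  expect_equal(final, 50, tolerance = 1e-5)
  expect_equal(unname(tr@amounts[1, "A"]), 100)
})

test_that("zero-rate network stays constant at the initial state", {
  net <- toyRhsNetwork()
  p <- parameterValues(defaultParameters(net))
  p[] <- 0
  # mass action with k = 0 would violate positivity checks; use tiny eps
  p[] <- 1e-300
  tr <- simulateModel(net, p, tEnd = 5)
  for (s in colnames(tr@amounts))
    expect_equal(unname(tr@amounts[, s]),
                 rep(unname(tr@amounts[1, s]), nrow(tr@amounts)),
                 tolerance = 1e-9)
})

test_that("finite-difference slopes agree with the assembled RHS", {
  m <- defaultModel()
  # a dynamically active segment: first hour of reoxygenation
  ogd <- runProtocol(m$network, m$params, m$state,
                     makeOGDRProtocol(6, 0.01))
  st <- ogd@amounts[nrow(ogd@amounts), ]
  st["O2"] <- 0.21; st["Glc"] <- 5.05
  dt <- 0.0005
  tr <- simulateModel(m$network, m$params, st, tEnd = 1,
                      times = seq(0, 1, dt),
                      settings = simSettings(rtol = 1e-9, atol = 1e-11))
  rhs <- assembleRHS(m$network, m$params)
  set.seed(7)
  idx <- sample(2:(nrow(tr@amounts) - 1), 20)
  for (i in idx) {
    fd <- (tr@amounts[i + 1, ] - tr@amounts[i - 1, ]) / (2 * dt)
    an <- rhs(tr@amounts[i, ])
    scale <- pmax(abs(an), 1e-4 * pmax(tr@amounts[i, ], 1))
    active <- abs(an) > 1e-8 * pmax(tr@amounts[i, ], 1)
    expect_lt(max(abs(fd - an)[active] / scale[active]), 1e-3)
  }
})

test_that("amounts remain nonnegative (within clamp tolerance) under OGD/R", {
  tr <- cachedOGDR()
  expect_true(all(tr@amounts >= 0))
  expect_lt(tr@clampCount / length(tr@amounts), 1e-3)
})

test_that("structural pools are conserved through the OGD/R protocol", {
  tr <- cachedOGDR()
  pools <- list(c("TNFR", "TNFR_act"), c("TLR4", "TLR4_act"),
                c("VEGFR", "VEGFR_pY1175", "VEGFR_pY951"),
                c("NFkB_IkB", "NFkB_nuc"),
                c("Ca_cyt", "Ca_ER"), c("ATP", "AMP"),
                c("BH4", "BH2"), c("AMPK", "AMPKp"))
  for (pool in pools) {
    tot <- rowSums(tr@amounts[, pool, drop = FALSE])
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6,
              label = paste("conservation of", paste(pool, collapse = "+")))
  }
})

test_that("solver failure reports the offending species", {
  # explosive self-amplification: A -> 2A at huge rate
  b <- networkBuilder()
  addSpecies(b, "A", "cytosol", 1, "relative")
  addReaction(b, "k_boom", "metabolism", reactants = c(A = 1),
              products = c(A = 2),
              law = rateLaw("mass_action", "k_boom"), k = 50)
  net <- finalizeNetwork(b, balance = FALSE)
  suppressWarnings(
    expect_error(simulateModel(net, defaultParameters(net), tEnd = 50),
                 "simulation error"))
})

test_that("trajectory CSV export is tidy and complete", {
  net <- toyPairNetwork()
  tr <- simulateModel(net, defaultParameters(net), tEnd = 2)
  f <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(tr, f)
  df <- read.csv(f)
  expect_identical(names(df), c("time", "species", "amount", "phase"))
  expect_equal(nrow(df), length(tr@times) * ncol(tr@amounts))
})

test_that("SBML export carries one kinetic law per reaction and validates", {
  # trivial toy network
  net <- toyDecayNetwork()
  doc <- exportSBML(net, defaultParameters(net), initialState(net))
  x <- xml2::read_xml(doc)
  expect_identical(xml2::xml_name(x), "sbml")
  expect_identical(xml2::xml_attr(x, "level"), "3")
  expect_identical(xml2::xml_attr(x, "version"), "2")
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  laws <- xml2::xml_find_all(x, "//s:reaction/s:kineticLaw", ns)
  expect_length(laws, 1)
  # default network: kinetic law count equals reaction count
  m <- defaultModel()
  doc2 <- exportSBML(m$network, m$params, m$state)
  x2 <- xml2::read_xml(doc2)
  expect_length(xml2::xml_find_all(x2, "//s:reaction/s:kineticLaw", ns),
                length(m$network@reactions))
  expect_length(xml2::xml_find_all(x2, "//s:species", ns),
                nrow(m$network@species))
})

test_that("SBML round trip is exact and idempotent", {
  m <- defaultModel()
  f1 <- tempfile(fileext = ".xml")
  exportSBML(m$network, m$params, m$state, file = f1)
  back <- importSBML(f1)
  f2 <- tempfile(fileext = ".xml")
  exportSBML(back$network, back$params, back$state, file = f2)
  expect_identical(readLines(f1), readLines(f2))
  # re-simulation agreement within 1e-6 relative on a 24 h control run
  tr1 <- simulateModel(m$network, m$params, m$state, 24)
  tr2 <- simulateModel(back$network, back$params, back$state, 24)
  rel <- abs(tr2@amounts - tr1@amounts) /
    pmax(abs(tr1@amounts), 1e-9)
  expect_lt(max(rel), 1e-6)
})

test_that("YAML config round trip reconstructs the model exactly", {
  m <- defaultModel()
  f <- tempfile(fileext = ".yaml")
  writeNetworkConfig(m$network, f, m$params, m$state)
  back <- readNetworkConfig(f)
  expect_equal(parameterValues(back$params), parameterValues(m$params),
               tolerance = 1e-12)
  expect_identical(speciesIds(back$network), speciesIds(m$network))
  expect_identical(reactionIds(back$network), reactionIds(m$network))
  expect_equal(back$state, m$state, tolerance = 1e-12)
})
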