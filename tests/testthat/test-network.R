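test_that("default network wiring realizes the pathway checklist", {
  m <- defaultModel()
  edges <- causalEdges(m$network)
  paths <- list(
    # inflammation: receptor -> NFkB -> cytokines, MAPK branch, A20 feedback
    c("LPS", "IL6"), c("TNFa", "IL6"), c("TNFa", "CCL2"),
    c("NFkB_nuc", "A20"), c("A20", "TRAF6_Ub"), c("A20", "RIPK1_Ub"),
    c("TAK1p", "p38p"), c("TAK1p", "JNKp"), c("TAK1p", "ERKp"),
    # survival: VEGFR site-specific branches, Tie2, FGFR, Wnt, calcium
    c("VEGF", "ERKp"), c("VEGF", "AKTp"), c("VEGF", "eNOSp"),
    c("PLCgp", "ULKp"), c("Ang1", "AKTp"), c("Ang1", "ERKp"),
    c("FGF", "AKTp"), c("FGF", "ZO1"), c("FGF", "ERKp"),
    c("Wnt", "bCatenin"),
    # hypoxia: O2 -> PHD -> HIFs -> targets and p53 axis
    c("O2", "PHD"), c("PHD", "HIF1a"), c("HIF1a_nuc", "BDNF"),
    c("HIF2a_nuc", "Ang2"), c("HIF1a_nuc", "Casp3"), c("p53", "MDM2"),
    c("MDM2", "p53"), c("p53", "NADPH"), c("p53", "Casp3"),
    # metabolism
    c("Glc", "ATP"), c("O2", "ATP"), c("ATP", "AMPKp"), c("O2", "PFKFB3"),
    # oxidative stress core
    c("O2", "Succinate"), c("Succinate", "ROS"), c("ROS", "iNOS"),
    c("iNOS", "NO"), c("NO", "ONOO"), c("ROS", "BH2"), c("BH2", "ROS"),
    c("ROS", "NRF2act"), c("NRF2act", "ROS"), c("ROS", "ZO1"),
    c("ROS", "Claudin5"), c("ROS", "IL6"), c("ROS", "Ca_cyt"))
  for (p in paths)
    expect_true(hasCausalPath(edges, p[1], p[2]),
                label = paste("causal path", p[1], "->", p[2]))
})

test_that("the ROS -> IKK activation reaction is present explicitly", {
  m <- defaultModel()
  r <- Filter(function(x) x$id == "kp_IKK_ROS", m$network@reactions)
  expect_length(r, 1)
  expect_equal(names(r[[1]]$products), "IKKp")
  regs <- vapply(r[[1]]$law$regulators, `[[`, character(1), "species")
  expect_true("ROS" %in% regs)
})

test_that("stoichiometry matrix matches an independent recount", {
  m <- defaultModel()
  N <- stoichiometryMatrix(m$network)
  expect_identical(dim(N), c(nrow(m$network@species),
                             length(m$network@reactions)))
  # brute-force recount from the declared reaction lists
  for (j in sample(seq_along(m$network@reactions), 25)) {
    r <- m$network@reactions[[j]]
    expected <- numeric(nrow(m$network@species))
    names(expected) <- m$network@species$id
    for (s in names(r$reactants)) expected[s] <- expected[s] - r$reactants[[s]]
    for (s in names(r$products)) expected[s] <- expected[s] + r$products[[s]]
    expect_equal(unname(N[, j]), unname(expected))
  }
  expect_true(all(N == round(N)))
})

test_that("network validity rejects degenerate constructions", {
  # a species participating in no reaction is rejected
  b <- networkBuilder()
  addSpecies(b, "A", "cytosol", 1, "relative")
  addSpecies(b, "Orphan", "cytosol", 1, "relative")
  addReaction(b, "kd_A", "metabolism", reactants = c(A = 1),
              law = rateLaw("first_order_decay", "kd_A"), k = 1)
  expect_error(finalizeNetwork(b, balance = FALSE), "participate")
  # reactions with both sides empty are rejected
  b2 <- networkBuilder()
  addSpecies(b2, "A", "cytosol", 1, "relative")
  b2$reactions[[1]] <- list(id = "null", module = "metabolism",
                            reactants = numeric(0), products = numeric(0),
                            law = rateLaw("mass_action", "k0"))
  b2$fixed["k0"] <- 1
  expect_error(finalizeNetwork(b2, balance = FALSE), "both empty")
})

test_that("species tagged as markers form the canonical panel", {
  m <- defaultModel()
  roles <- strsplit(m$network@species$roles, ",", fixed = TRUE)
  tagged <- m$network@species$id[vapply(roles, function(r)
    "marker" %in% r, logical(1))]
  expect_setequal(tagged, markerIds())
  expect_length(markerIds(), 12)
})

test_that("default bounds bracket each rate constant at 0.5x and 2x", {
  m <- defaultModel()
  b <- parameterBounds(m$params)
  v <- parameterValues(m$params)
  expect_equal(unname(b[, "low"]), unname(v) * 0.5)
  expect_equal(unname(b[, "high"]), unname(v) * 2)
  expect_true(all(v > 0))
})

test_that("assembleRHS reproduces closed-form fluxes", {
  net <- toyRhsNetwork()
  rhs <- assembleRHS(net, defaultParameters(net))
  d <- rhs(initialState(net))
  # mass action A -> B with k = 1, A = 2
  expect_equal(d[["A"]], -2)
  expect_equal(d[["B"]], 2)
  # Hill activation at half saturation (X = K = 5): flux = k / 2
  expect_equal(d[["P"]], 2)
  # unresolved parameter id is named in the error
  expect_error(assembleRHS(net, c(k_ab = 1)), "k_p")
})

test_that("RHS is finite and conservative for arbitrary nonnegative states", {
  m <- defaultModel()
  rhs <- assembleRHS(m$network, m$params)
  set.seed(1)
  for (i in 1:5) {
    s <- initialState(m$network) * stats::runif(nrow(m$network@species), 0, 3)
    d <- rhs(s)
    expect_true(all(is.finite(d)))
  }
  # zero state: only pure synthesis terms can be positive, nothing negative
  d0 <- rhs(initialState(m$network) * 0)
  expect_true(all(d0 >= 0))
})

test_that("metadata records the published model scale as descriptive only", {
  m <- defaultModel()
  counts <- m$network@metadata$reference_counts
  expect_identical(unname(counts["species"]), 108L)
  expect_identical(unname(counts["reactions"]), 145L)
})
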