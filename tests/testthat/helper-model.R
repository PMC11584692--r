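# Shared fixtures: the default model and a few hand-sized toy networks.
# Expensive objects are memoized for the whole test run.

.cache <- new.env(parent = emptyenv())

defaultModel <- function() {
  if (is.null(.cache$model)) {
    net <- buildDefaultNetwork()
    .cache$model <- list(network = net,
                         params = defaultParameters(net),
                         state = initialState(net))
  }
  .cache$model
}

# OGD 6 h / reoxygenation 24 h trajectory of the default model
cachedOGDR <- function() {
  if (is.null(.cache$ogdr)) {
    m <- defaultModel()
    .cache$ogdr <- runProtocol(m$network, m$params, m$state,
                               makeOGDRProtocol(6, 24))
  }
  .cache$ogdr
}

# single species with first-order decay, not at steady state
toyDecayNetwork <- function(kd = log(2), A0 = 100) {
  b <- networkBuilder()
  addSpecies(b, "A", "cytosol", A0, "relative")
  addReaction(b, "kd_A", "metabolism", reactants = c(A = 1),
              law = rateLaw("first_order_decay", "kd_A"), k = kd)
  finalizeNetwork(b, balance = FALSE)
}

# zeroth-order synthesis + first-order decay; analytic steady state
# k_syn / k_deg
toyPairNetwork <- function(ksyn = 50, kdeg = 0.5) {
  b <- networkBuilder()
  addSpecies(b, "P", "cytosol", ksyn / kdeg, "relative")
  addReaction(b, "kt_P", "metabolism", products = c(P = 1),
              law = rateLaw("zeroth_order_synthesis", "kt_P"), k = ksyn)
  addReaction(b, "kd_P", "metabolism", reactants = c(P = 1),
              law = rateLaw("first_order_decay", "kd_P"), k = kdeg)
  finalizeNetwork(b, balance = FALSE)
}

# A -> B mass action plus Hill-activated synthesis of P by X
toyRhsNetwork <- function() {
  b <- networkBuilder()
  addSpecies(b, "A", "cytosol", 2, "relative")
  addSpecies(b, "B", "cytosol", 0, "relative")
  addSpecies(b, "X", "cytosol", 5, "relative")
  addSpecies(b, "P", "cytosol", 0, "relative")
  addReaction(b, "k_ab", "metabolism", reactants = c(A = 1),
              products = c(B = 1),
              law = rateLaw("mass_action", "k_ab"), k = 1)
  addReaction(b, "k_p", "metabolism", products = c(P = 1),
              law = rateLaw("hill_activation", "k_p",
                            list(reg("X", "act", 5, 1, relative = FALSE))),
              k = 4)
  addReaction(b, "kd_x", "metabolism", reactants = c(X = 1),
              law = rateLaw("first_order_decay", "kd_x"), k = 1e-12)
  finalizeNetwork(b, balance = FALSE)
}

# directed causal reachability over the reaction graph: regulators and
# reactants influence products; regulators also influence the reactants
# they consume/degrade
causalEdges <- function(network) {
  edges <- list()
  for (r in network@reactions) {
    sources <- c(names(r$reactants),
                 vapply(r$law$regulators, `[[`, character(1), "species"))
    targets <- names(r$products)
    for (s in sources) for (p in targets)
      edges[[length(edges) + 1L]] <- c(s, p)
    for (m in vapply(r$law$regulators, `[[`, character(1), "species"))
      for (p in names(r$reactants))
        edges[[length(edges) + 1L]] <- c(m, p)
  }
  unique(do.call(rbind, edges))
}

hasCausalPath <- function(edges, from, to) {
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(edges[edges[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  to %in% seen
}

# hand-built trajectory over given marker values (constant in time)
syntheticTrajectory <- function(values, times = c(0, 1, 2)) {
  m <- matrix(rep(values, each = length(times)), nrow = length(times),
              dimnames = list(NULL, names(values)))
  new("Trajectory", times = times, amounts = m,
      phaseMarks = data.frame(time = 0, phase = "stimulus",
                              stringsAsFactors = FALSE),
      clampCount = 0L)
}
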