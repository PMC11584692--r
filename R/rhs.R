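#' @include network-build.R
NULL

# Precompile a network into index arrays for fast flux evaluation.
# Reactant mass-action terms support up to two distinct reactant species
# (stoichiometry as exponent); regulators are laid out in up to four
# multiplicative "slots" so the whole flux vector is computed with a few
# vectorized operations.
.compileNetwork <- function(net) {
  sp <- net@species$id
  rx <- net@reactions
  nr <- length(rx)
  ra <- rep(1L, nr); rae <- rep(0, nr)
  rb <- rep(1L, nr); rbe <- rep(0, nr)
  rxnParam <- character(nr)
  regRows <- list()
  for (j in seq_len(nr)) {
    r <- rx[[j]]
    rxnParam[j] <- r$law$param
    rs <- r$reactants
    if (length(rs) > 2) stop("at most two distinct reactant species supported")
    if (length(rs) >= 1) { ra[j] <- match(names(rs)[1], sp); rae[j] <- rs[[1]] }
    if (length(rs) == 2) { rb[j] <- match(names(rs)[2], sp); rbe[j] <- rs[[2]] }
    for (g in r$law$regulators)
      regRows[[length(regRows) + 1L]] <-
        list(rxn = j, spi = match(g$species, sp),
             inh = identical(g$mode, "inh"), K = g$K, n = g$n)
    if (identical(r$law$kind, "michaelis_menten")) {
      # saturation on the single reactant: k * S / (Km + S)
      if (length(rs) != 1 || rs[[1]] != 1)
        stop("michaelis_menten needs exactly one unit-stoichiometry reactant")
      rae[j] <- 0
      regRows[[length(regRows) + 1L]] <-
        list(rxn = j, spi = ra[j], inh = FALSE, K = r$law$Km, n = 1)
    }
  }
  # distribute regulator rows into slots: one slot never hits a reaction twice
  slots <- list()
  used <- integer(nr)
  for (row in regRows) {
    placed <- FALSE
    for (s in seq_along(slots)) {
      if (!(row$rxn %in% slots[[s]]$rxn)) {
        slots[[s]]$rxn <- c(slots[[s]]$rxn, row$rxn)
        slots[[s]]$spi <- c(slots[[s]]$spi, row$spi)
        slots[[s]]$inh <- c(slots[[s]]$inh, row$inh)
        slots[[s]]$Kn <- c(slots[[s]]$Kn, row$K^row$n)
        slots[[s]]$n <- c(slots[[s]]$n, row$n)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      slots[[length(slots) + 1L]] <-
        list(rxn = row$rxn, spi = row$spi, inh = row$inh,
             Kn = row$K^row$n, n = row$n)
  }
  paramIds <- rxnParam
  N <- stoichiometryMatrix(net)
  storage.mode(N) <- "double"
  clampIdx <- match(net@metadata$clamped, sp)
  list(sp = sp, nr = nr, ra = ra, rae = rae, rb = rb, rbe = rbe,
       rxnParam = rxnParam, paramIds = paramIds, slots = slots, N = N,
       clampIdx = clampIdx[!is.na(clampIdx)])
}

# Flux vector at a state; params is a named vector over reaction parameters.
.evalFlux <- function(comp, state, params) {
  y <- pmax(as.numeric(state), 0)
  f <- unname(params[comp$rxnParam])
  f <- f * y[comp$ra]^comp$rae * y[comp$rb]^comp$rbe
  for (s in comp$slots) {
    yv <- y[s$spi]^s$n
    h <- yv / (s$Kn + yv)
    h[s$inh] <- 1 - h[s$inh]
    f[s$rxn] <- f[s$rxn] * h
  }
  f
}

#' Assemble the ODE right-hand side of a network
#'
#' Returns a deterministic derivative evaluator mapping (state, time) to
#' d(state)/dt. Each reaction's flux contributes +stoichiometry to its
#' products and -stoichiometry to its reactants; clamped environment
#' species keep zero derivative. States are floored at zero before flux
#' evaluation so all fluxes are finite and nonnegative for any
#' nonnegative state.
#'
#' @param network a ReactionNetwork.
#' @param params a ParameterSet (or named numeric). Every reaction
#'   parameter must resolve; an unresolved id raises an error naming it.
#' @return function(state, t = 0) returning the named derivative vector.
#' @export
assembleRHS <- function(network, params = defaultParameters(network)) {
  comp <- .compileNetwork(network)
  pv <- if (is(params, "ParameterSet")) params@values else params
  missing <- setdiff(unique(comp$rxnParam), names(pv))
  if (length(missing))
    stop("unresolved parameter id(s): ", paste(missing, collapse = ", "))
  pvec <- pv[comp$rxnParam]
  N <- comp$N
  clampIdx <- comp$clampIdx
  slots <- comp$slots
  ra <- comp$ra; rae <- comp$rae; rb <- comp$rb; rbe <- comp$rbe
  sp <- comp$sp
  function(state, t = 0) {
    y <- pmax(as.numeric(state), 0)
    f <- unname(pvec) * y[ra]^rae * y[rb]^rbe
    for (s in slots) {
      yv <- y[s$spi]^s$n
      h <- yv / (s$Kn + yv)
      h[s$inh] <- 1 - h[s$inh]
      f[s$rxn] <- f[s$rxn] * h
    }
    dy <- as.vector(N %*% f)
    if (length(clampIdx)) dy[clampIdx] <- 0
    names(dy) <- sp
    dy
  }
}

#' Per-reaction fluxes at a state
#' @param network a ReactionNetwork.
#' @param params ParameterSet or named numeric.
#' @param state named state vector.
#' @return named numeric vector of reaction fluxes.
#' @export
reactionFluxes <- function(network, params, state) {
  comp <- .compileNetwork(network)
  pv <- if (is(params, "ParameterSet")) params@values else params
  state <- state[comp$sp]
  stats::setNames(.evalFlux(comp, state, pv), reactionIds(network))
}
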