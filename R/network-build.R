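#' @include AllGenerics.R
NULL

#' Describe a regulator of a reaction rate
#'
#' Regulators multiply the rate by a Hill term without being consumed.
#' Activation: x^n / (K^n + x^n); inhibition: K^n / (K^n + x^n). K may be
#' given relative to the regulator's baseline amount (the usual case for
#' intracellular species) or as an absolute amount (ligands, O2, glucose).
#'
#' @param species regulator species id.
#' @param mode "act" or "inh".
#' @param K half-saturation constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @param relative if TRUE, K is a multiple of the regulator baseline and is
#'   converted to absolute units when the network is finalized.
#' @return regulator description list.
#' @export
reg <- function(species, mode = c("act", "inh"), K, n = 1, relative = TRUE) {
  mode <- match.arg(mode)
  stopifnot(K > 0, n >= 1)
  list(species = species, mode = mode, K = K, n = n, relative = relative)
}

#' Construct a rate law
#'
#' Flux = rate_constant * prod(reactant^stoich) * prod(regulator Hill terms).
#' \code{michaelis_menten} applies K_m saturation to the (single) reactant.
#'
#' @param kind one of mass_action, hill_activation, hill_inhibition,
#'   michaelis_menten, zeroth_order_synthesis, first_order_decay.
#' @param param rate constant identifier (resolved in the ParameterSet).
#' @param regulators list of \code{\link{reg}} descriptions.
#' @param Km Michaelis constant (michaelis_menten only, absolute units).
#' @return rate law list.
#' @export
rateLaw <- function(kind, param, regulators = list(), Km = NULL) {
  stopifnot(kind %in% .RATE_KINDS)
  if (kind %in% c("hill_activation", "hill_inhibition")) {
    if (!length(regulators))
      stop("hill rate laws need at least one regulator")
    want <- if (kind == "hill_activation") "act" else "inh"
    if (regulators[[1]]$mode != want)
      stop("first regulator mode must match the hill kind")
  }
  if (kind == "michaelis_menten" && is.null(Km))
    stop("michaelis_menten needs Km")
  list(kind = kind, param = param, regulators = regulators, Km = Km)
}

#' Start an empty network builder
#' @return builder environment for \code{\link{addSpecies}} /
#'   \code{\link{addReaction}} / \code{\link{finalizeNetwork}}.
#' @export
networkBuilder <- function() {
  b <- new.env(parent = emptyenv())
  b$species <- list()
  b$reactions <- list()
  b$balancers <- character(0)
  b$fixed <- numeric(0)      # provisional rate constants
  b$clamped <- character(0)  # environment inputs with zero derivative
  b
}

#' Register a species
#' @param b builder from \code{\link{networkBuilder}}.
#' @param id unique species id.
#' @param compartment one of cytosol, nucleus, ER, mitochondrion, membrane,
#'   medium, environment.
#' @param baseline nonnegative initial amount (copies per cell for proteins,
#'   relative units for metabolites/radicals, fraction for O2, mmol/L for
#'   glucose).
#' @param unit unit label.
#' @param roles character vector of role tags.
#' @param clamped if TRUE the derivative is forced to zero (environment
#'   inputs set per protocol phase).
#' @return the builder, invisibly.
#' @export
addSpecies <- function(b, id, compartment, baseline, unit = "copies_per_cell",
                       roles = character(0), clamped = FALSE) {
  if (id %in% names(b$species)) stop("duplicate species id: ", id)
  b$species[[id]] <- list(id = id, compartment = compartment,
                          baseline = baseline, unit = unit,
                          roles = paste(roles, collapse = ","))
  if (clamped) b$clamped <- c(b$clamped, id)
  invisible(b)
}

#' Register a reaction
#'
#' @param b builder.
#' @param id unique reaction id.
#' @param module pathway module label.
#' @param reactants,products named numeric stoichiometries (names are
#'   species ids); either may be empty.
#' @param law a \code{\link{rateLaw}}.
#' @param k provisional rate constant; ignored (recomputed) if this reaction
#'   balances a species.
#' @param balances species id whose steady-state balance determines this
#'   reaction's rate constant, or NULL.
#' @return the builder, invisibly.
#' @export
addReaction <- function(b, id, module, reactants = numeric(0),
                        products = numeric(0), law, k = 1, balances = NULL) {
  rids <- vapply(b$reactions, `[[`, character(1), "id")
  if (id %in% rids) stop("duplicate reaction id: ", id)
  if (law$param %in% names(b$fixed)) stop("duplicate parameter id: ", law$param)
  b$reactions[[length(b$reactions) + 1L]] <-
    list(id = id, module = module, reactants = reactants,
         products = products, law = law)
  b$fixed[law$param] <- k
  if (!is.null(balances)) {
    if (balances %in% names(b$balancers))
      stop("species ", balances, " already has a balancing parameter")
    b$balancers[balances] <- law$param
  }
  invisible(b)
}

.speciesTable <- function(b) {
  do.call(rbind, lapply(b$species, function(s)
    data.frame(id = s$id, compartment = s$compartment, baseline = s$baseline,
               unit = s$unit, roles = s$roles, stringsAsFactors = FALSE)))
}

#' Finalize a builder into a balanced ReactionNetwork
#'
#' Converts relative regulator K values to absolute units, then solves the
#' designated balancing rate constants so that the declared baseline state
#' is an exact steady state of the assembled ODE system under the control
#' environment. Balancing sweeps the species list repeatedly, solving the
#' (linear) one-parameter balance per species, until the largest relative
#' net flux falls below \code{tol}.
#'
#' @param b builder.
#' @param metadata extra metadata entries.
#' @param tol relative net-flux tolerance for steady-state acceptance.
#' @param maxSweeps maximum balancing sweeps.
#' @param balance if FALSE, skip steady-state balancing and keep the
#'   declared rate constants (for networks not meant to start at steady
#'   state).
#' @return a validated \code{ReactionNetwork} whose metadata carries the
#'   default \code{ParameterSet}.
#' @export
finalizeNetwork <- function(b, metadata = list(), tol = 1e-10,
                            maxSweeps = 500L, balance = TRUE) {
  sp <- .speciesTable(b)
  rownames(sp) <- NULL
  base <- stats::setNames(sp$baseline, sp$id)
  reactions <- lapply(b$reactions, function(r) {
    r$law$regulators <- lapply(r$law$regulators, function(g) {
      if (isTRUE(g$relative)) {
        g$K <- g$K * base[[g$species]]
        g$relative <- FALSE
      }
      g
    })
    r
  })
  labels <- stats::setNames(vapply(reactions, `[[`, character(1), "module"),
                            vapply(reactions, `[[`, character(1), "id"))
  net <- new("ReactionNetwork", species = sp, reactions = reactions,
             moduleLabels = labels, balancers = b$balancers,
             metadata = list(clamped = b$clamped))
  params <- b$fixed
  if (!balance) {
    bounds <- cbind(low = params * 0.5, high = params * 2)
    pset <- new("ParameterSet", values = params, bounds = bounds)
    net@metadata <- c(list(parameters = pset, clamped = b$clamped), metadata)
    validObject(net)
    return(net)
  }
  comp <- .compileNetwork(net)
  scale <- pmax(base, 1e-12)

  balSpecies <- names(b$balancers)
  balParam <- unname(b$balancers)
  pidx <- match(balParam, comp$paramIds)
  if (anyNA(pidx)) stop("balancing parameter not found in parameter list")
  # reaction index carrying each balancing parameter
  brxn <- match(balParam, comp$rxnParam)
  N <- comp$N

  for (sweep in seq_len(maxSweeps)) {
    for (i in seq_along(balSpecies)) {
      s <- balSpecies[i]
      si <- match(s, sp$id)
      flux <- .evalFlux(comp, base, params)
      own <- flux[brxn[i]]
      unit <- own / params[[balParam[i]]]
      sign <- N[si, brxn[i]]
      if (unit <= 0 || sign == 0)
        stop("cannot balance species ", s, ": zero unit flux or stoichiometry")
      others <- sum(N[si, ] * flux) - sign * own
      knew <- -others / (sign * unit)
      if (!is.finite(knew) || knew <= 0)
        stop("balancing species ", s, " requires a nonpositive rate constant (",
             signif(knew, 4), "); adjust fixed rates")
      params[[balParam[i]]] <- knew
    }
    flux <- .evalFlux(comp, base, params)
    resid <- as.vector(N %*% flux) / scale
    resid[match(b$clamped, sp$id)] <- 0
    if (max(abs(resid)) < tol) break
    if (sweep == maxSweeps)
      stop("steady-state balancing did not converge; worst species: ",
           sp$id[which.max(abs(resid))], " (relative net flux ",
           signif(max(abs(resid)), 3), ")")
  }

  bounds <- cbind(low = params * 0.5, high = params * 2)
  pset <- new("ParameterSet", values = params, bounds = bounds)
  net@metadata <- c(list(parameters = pset, clamped = b$clamped), metadata)
  validObject(net)
  validObject(pset)
  net
}

#' Build a ParameterSet
#' @param values named positive numeric vector.
#' @param bounds optional matrix (low, high); default 0.5x-2x of values.
#' @return a ParameterSet.
#' @export
parameterSet <- function(values, bounds = NULL) {
  if (is.null(bounds))
    bounds <- cbind(low = values * 0.5, high = values * 2)
  new("ParameterSet", values = values, bounds = bounds)
}

#' Replace parameter values (bounds kept, widened where needed)
#' @param params a ParameterSet.
#' @param values named numeric of replacement values.
#' @param rescaleBounds if TRUE bounds are reset to 0.5x-2x of new values.
#' @return updated ParameterSet.
#' @export
updateParameters <- function(params, values, rescaleBounds = FALSE) {
  v <- params@values
  unknown <- setdiff(names(values), names(v))
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
  v[names(values)] <- values
  b <- params@bounds
  if (rescaleBounds) {
    b <- cbind(low = v * 0.5, high = v * 2)
  } else {
    b[names(values), "low"] <- pmin(b[names(values), "low"], values)
    b[names(values), "high"] <- pmax(b[names(values), "high"], values)
  }
  new("ParameterSet", values = v, bounds = b)
}

#' Scale parameters by named multipliers
#' @param params a ParameterSet.
#' @param multipliers named numeric multipliers.
#' @return updated ParameterSet (bounds widened to contain new values).
#' @export
scaleParameters <- function(params, multipliers) {
  updateParameters(params,
                   params@values[names(multipliers)] * multipliers)
}
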