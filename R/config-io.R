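#' @include fixtures.R
NULL

#' Serialize a model to a structured config list
#'
#' Sections: species, reactions, parameters, environment (clamped inputs
#' and control values), plus balancer and metadata records so the model
#' can be reconstructed exactly without rebalancing.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet.
#' @param state initial state (default: network baseline).
#' @return nested list suitable for YAML serialization.
#' @export
networkToConfig <- function(network, params = defaultParameters(network),
                            state = initialState(network)) {
  sp <- network@species
  species <- lapply(seq_len(nrow(sp)), function(i)
    list(id = sp$id[i], compartment = sp$compartment[i],
         baseline = sp$baseline[i], unit = sp$unit[i],
         roles = sp$roles[i], initial = unname(state[sp$id[i]])))
  reactions <- lapply(network@reactions, function(r)
    list(id = r$id, module = unname(network@moduleLabels[r$id]),
         reactants = as.list(r$reactants), products = as.list(r$products),
         law = list(kind = r$law$kind, param = r$law$param,
                    Km = r$law$Km,
                    regulators = lapply(r$law$regulators, function(g)
                      list(species = g$species, mode = g$mode,
                           K = g$K, n = g$n)))))
  list(species = species, reactions = reactions,
       parameters = list(values = as.list(params@values),
                         low = as.list(params@bounds[, "low"]),
                         high = as.list(params@bounds[, "high"])),
       environment = list(clamped = as.list(network@metadata$clamped),
                          control = controlEnvironment()),
       balancers = as.list(network@balancers))
}

#' Reconstruct a model from a config list
#' @param config list from \code{\link{networkToConfig}}.
#' @return list(network, params, state).
#' @export
configToNetwork <- function(config) {
  sp <- do.call(rbind, lapply(config$species, function(s)
    data.frame(id = s$id, compartment = s$compartment,
               baseline = s$baseline, unit = s$unit, roles = s$roles,
               stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  reactions <- lapply(config$reactions, function(r)
    list(id = r$id,
         reactants = unlist(r$reactants) %||% numeric(0),
         products = unlist(r$products) %||% numeric(0),
         law = list(kind = r$law$kind, param = r$law$param,
                    Km = r$law$Km,
                    regulators = lapply(r$law$regulators, function(g)
                      list(species = g$species, mode = g$mode, K = g$K,
                           n = g$n, relative = FALSE)))))
  labels <- stats::setNames(
    vapply(config$reactions, function(r) r$module, character(1)),
    vapply(config$reactions, function(r) r$id, character(1)))
  values <- unlist(config$parameters$values)
  bounds <- cbind(low = unlist(config$parameters$low),
                  high = unlist(config$parameters$high))
  rownames(bounds) <- names(values)
  pset <- new("ParameterSet", values = values, bounds = bounds)
  net <- new("ReactionNetwork", species = sp, reactions = reactions,
             moduleLabels = labels,
             balancers = unlist(config$balancers) %||% character(0),
             metadata = list(parameters = pset,
                             clamped = unlist(config$environment$clamped) %||%
                               character(0)))
  validObject(net)
  state <- stats::setNames(
    vapply(config$species, function(s) s$initial, numeric(1)),
    vapply(config$species, function(s) s$id, character(1)))
  list(network = net, params = pset, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model config as YAML
#' @param network a ReactionNetwork.
#' @param file output path.
#' @param params ParameterSet.
#' @param state initial state.
#' @return the path, invisibly.
#' @export
writeNetworkConfig <- function(network, file,
                               params = defaultParameters(network),
                               state = initialState(network)) {
  yaml::write_yaml(networkToConfig(network, params, state), file,
                   precision = 15)
  invisible(file)
}

#' Read a model config from YAML
#' @param file YAML path.
#' @return list(network, params, state).
#' @export
readNetworkConfig <- function(file) {
  configToNetwork(yaml::read_yaml(file))
}
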