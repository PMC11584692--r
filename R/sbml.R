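#' @include config-io.R
NULL

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.BMEC_NS <- "https://bmecsim.org/sbml-annotation"

.sanitizeId <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  bad <- !grepl("^[A-Za-z_]", out)
  out[bad] <- paste0("x_", out[bad])
  out
}

.num <- function(x) sprintf("%.15g", x)

.mathHill <- function(species, mode, K, n) {
  xn <- sprintf("<apply><power/><ci> %s </ci><cn> %s </cn></apply>",
                species, .num(n))
  Kn <- sprintf("<apply><power/><cn> %s </cn><cn> %s </cn></apply>",
                .num(K), .num(n))
  numerator <- if (mode == "act") xn else Kn
  sprintf("<apply><divide/>%s<apply><plus/>%s%s</apply></apply>",
          numerator, Kn, xn)
}

.kineticMath <- function(r) {
  terms <- sprintf("<ci> %s </ci>", r$law$param)
  for (s in names(r$reactants)) {
    st <- r$reactants[[s]]
    terms <- c(terms, if (st == 1) sprintf("<ci> %s </ci>", s)
               else sprintf("<apply><power/><ci> %s </ci><cn> %s </cn></apply>",
                            s, .num(st)))
  }
  if (identical(r$law$kind, "michaelis_menten")) {
    s <- names(r$reactants)[1]
    terms <- c(terms[1],
               sprintf("<apply><divide/><ci> %s </ci><apply><plus/><cn> %s </cn><ci> %s </ci></apply></apply>",
                       s, .num(r$law$Km), s))
  }
  for (g in r$law$regulators)
    terms <- c(terms, .mathHill(g$species, g$mode, g$K, g$n))
  body <- if (length(terms) == 1) terms else
    sprintf("<apply><times/>%s</apply>", paste(terms, collapse = ""))
  sprintf("<math xmlns=\"%s\">%s</math>", .MATHML_NS, body)
}

#' Export a model as SBML Level 3 Version 2
#'
#' Writes compartments, species (clamped environment inputs as boundary
#' species), global rate-constant parameters, and one reaction per
#' network reaction with its kinetic law as explicit MathML. The full
#' model config (including regulator constants, bounds and balancer
#' records) is embedded as a package annotation so that import and
#' round-trip are exact. Identifiers not expressible in SBML are
#' sanitized deterministically and the mapping recorded in the
#' annotation.
#'
#' @param network a ReactionNetwork.
#' @param params ParameterSet.
#' @param state initial state.
#' @param file optional output path.
#' @return the SBML document as a character string (invisibly if
#'   \code{file} given).
#' @export
exportSBML <- function(network, params = defaultParameters(network),
                       state = initialState(network), file = NULL) {
  # canonicalize all numerics through one YAML round trip so that the
  # annotation, the SBML attributes and any re-export agree byte for byte
  cfg0 <- networkToConfig(network, params, state)
  m <- configToNetwork(yaml::yaml.load(yaml::as.yaml(cfg0, precision = 15)))
  network <- m$network; params <- m$params; state <- m$state
  sp <- network@species
  ids <- sp$id
  sane <- .sanitizeId(ids)
  if (anyDuplicated(sane)) stop("id sanitization produced duplicates")
  map <- stats::setNames(sane, ids)
  clamped <- network@metadata$clamped
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  add("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">", .SBML_NS)
  add("  <model id=\"bmec_signaling\" name=\"BMEC multi-pathway signaling model\">")
  # exact-reconstruction annotation
  cfg <- networkToConfig(network, params, state)
  cfg$id_map <- as.list(map)
  add("    <annotation>")
  add("      <bmec:modelSpec xmlns:bmec=\"%s\"><![CDATA[", .BMEC_NS)
  add("%s", yaml::as.yaml(cfg, precision = 15))
  add("]]></bmec:modelSpec>")
  add("    </annotation>")
  add("    <listOfCompartments>")
  for (comp in sort(unique(sp$compartment)))
    add("      <compartment id=\"%s\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>",
        .sanitizeId(comp))
  add("    </listOfCompartments>")
  add("    <listOfSpecies>")
  for (i in seq_len(nrow(sp)))
    add(paste0("      <species id=\"%s\" compartment=\"%s\" initialAmount=\"%s\"",
               " hasOnlySubstanceUnits=\"true\" boundaryCondition=\"%s\"",
               " constant=\"false\"/>"),
        map[ids[i]], .sanitizeId(sp$compartment[i]), .num(state[ids[i]]),
        if (ids[i] %in% clamped) "true" else "false")
  add("    </listOfSpecies>")
  add("    <listOfParameters>")
  for (p in names(params@values))
    add("      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
        .sanitizeId(p), .num(params@values[[p]]))
  add("    </listOfParameters>")
  add("    <listOfReactions>")
  for (r in network@reactions) {
    add("      <reaction id=\"%s\" reversible=\"false\">", .sanitizeId(r$id))
    if (length(r$reactants)) {
      add("        <listOfReactants>")
      for (s in names(r$reactants))
        add("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
            map[s], .num(r$reactants[[s]]))
      add("        </listOfReactants>")
    }
    if (length(r$products)) {
      add("        <listOfProducts>")
      for (s in names(r$products))
        add("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
            map[s], .num(r$products[[s]]))
      add("        </listOfProducts>")
    }
    mods <- unique(vapply(r$law$regulators, `[[`, character(1), "species"))
    if (length(mods)) {
      add("        <listOfModifiers>")
      for (s in mods)
        add("          <modifierSpeciesReference species=\"%s\"/>", map[s])
      add("        </listOfModifiers>")
    }
    r2 <- r
    r2$reactants <- stats::setNames(as.numeric(r$reactants),
                                    map[names(r$reactants)])
    r2$law$regulators <- lapply(r$law$regulators, function(g) {
      g$species <- map[[g$species]]; g })
    r2$law$param <- .sanitizeId(r$law$param)
    add("        <kineticLaw>")
    add("          %s", .kineticMath(r2))
    add("        </kineticLaw>")
    add("      </reaction>")
  }
  add("    </listOfReactions>")
  add("  </model>")
  add("</sbml>")
  doc <- paste(L, collapse = "\n")
  xml2::read_xml(doc)  # well-formedness guard
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Import a model from an SBML document written by \code{exportSBML}
#'
#' Reads the embedded model-spec annotation and reconstructs the network,
#' parameters and initial state exactly. Documents without the annotation
#' (foreign SBML) are rejected with an informative error, as the generic
#' MathML subset is not parsed.
#'
#' @param file path to the SBML file (or an SBML string).
#' @return list(network, params, state).
#' @export
importSBML <- function(file) {
  doc <- if (file.exists(file)) xml2::read_xml(file) else xml2::read_xml(file)
  node <- xml2::xml_find_first(
    doc, "//bmec:modelSpec", ns = c(bmec = .BMEC_NS))
  if (inherits(node, "xml_missing"))
    stop("SBML document lacks the bmec model-spec annotation; ",
         "foreign SBML import is not supported")
  cfg <- yaml::yaml.load(xml2::xml_text(node))
  cfg$id_map <- NULL
  configToNetwork(cfg)
}
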