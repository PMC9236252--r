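#' Load a run configuration
#'
#' Reads a YAML key/value configuration describing a model run.  Recognized
#' keys: `variant` (`neuronal`/`proliferative`), `parameters` (named kinetic
#' overrides), `initial` (named initial-concentration overrides), `horizon`,
#' `step`, `seed`, `events` (list of `{time, mode, assignments}`), `formula`,
#' `objectives` (map, or a `"name -> value, ..."` string), `bounds` (map of
#' `[lower, upper]`), `resolution`, `output_dir`.  Unknown keys and
#' out-of-range values are rejected with the offending key named.
#'
#' @param path path to the YAML file.
#' @return A list of class `"cdt_config"` with resolved `params`
#'   ([cdt_params()]), `init` ([cdt_initial_state()]), `events` (list of
#'   [cdt_event()]), and the remaining settings with defaults applied.
#' @examples
#' cfg <- tempfile(fileext = ".yml")
#' writeLines("variant: neuronal", cfg)
#' load_config(cfg)$params
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("variant", "parameters", "initial", "horizon", "step", "seed",
             "events", "formula", "objectives", "bounds", "resolution",
             "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))

  variant <- raw$variant %||% "neuronal"
  if (!variant %in% c("neuronal", "proliferative"))
    stop("config key 'variant' must be neuronal or proliferative")
  params <- do.call(cdt_params, c(list(variant = variant),
                                  raw$parameters %||% list()))
  init <- do.call(cdt_initial_state, raw$initial %||% list())

  events <- lapply(raw$events %||% list(), function(e) {
    extra <- setdiff(names(e), c("time", "mode", "assignments"))
    if (length(extra))
      stop("unknown event key(s): ", paste(extra, collapse = ", "))
    do.call(cdt_event, c(list(time = e$time, mode = e$mode %||% "absolute"),
                         e$assignments))
  })

  horizon <- raw$horizon %||% 100
  if (!is.numeric(horizon) || horizon <= 0)
    stop("config key 'horizon' must be > 0")
  step <- raw$step %||% 0.1
  seed <- raw$seed %||% 1L

  objectives <- raw$objectives
  if (is.character(objectives)) objectives <- parse_objectives(objectives)
  if (is.list(objectives)) objectives <- unlist(objectives)

  bounds <- raw$bounds
  if (!is.null(bounds)) {
    bounds <- lapply(bounds, as.numeric)
    ok <- vapply(bounds, function(b) length(b) == 2 && b[1] < b[2], TRUE)
    if (!all(ok))
      stop("config key 'bounds' entries must be [lower, upper]: ",
           paste(names(bounds)[!ok], collapse = ", "))
  }

  structure(list(variant = variant, params = params, init = init,
                 events = events, horizon = horizon, step = step,
                 seed = as.integer(seed),
                 formula = raw$formula, objectives = objectives,
                 bounds = bounds, resolution = raw$resolution %||% 30,
                 output_dir = raw$output_dir %||% "."),
            class = "cdt_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Records everything needed to regenerate a result: the resolved
#' configuration, the seed, and package/R versions.
#'
#' @param path output file.
#' @param config a `"cdt_config"` (or any list).
#' @param seed the seed actually used.
#' @param outputs character vector of files produced.
#' @return `path`, invisibly.
#' @export
run_manifest <- function(path, config, seed, outputs = character()) {
  payload <- list(
    package = "tyrcycle",
    version = as.character(utils::packageVersion("tyrcycle")),
    r_version = R.version.string,
    seed = seed,
    params = as.list(unclass(config$params)),
    init = as.list(unclass(config$init)),
    settings = config[setdiff(names(config), c("params", "init", "events"))],
    outputs = outputs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------
# SBML Level 3 export / import

sbml_rate_mathml <- function(r) {
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  times <- function(...) paste0("<apply><times/>", paste0(...), "</apply>")
  plus <- function(...) paste0("<apply><plus/>", paste0(...), "</apply>")
  divide <- function(a, b) paste0("<apply><divide/>", a, b, "</apply>")
  switch(r$name,
    polym_detyr = times(ci("kp1"), ci("TubDetyr")),
    polym_tyr = times(ci("kp2"), ci("TubTyr")),
    depolym_detyr = divide(times(ci("km1"), ci("MTDetyr")),
                           plus(ci("mc1"), ci("MTDetyr"))),
    depolym_tyr = divide(times(ci("km2"), ci("MTTyr")),
                         plus(ci("mc2"), ci("MTTyr"))),
    detyrosination = times(ci("k1"), ci("MTTyr"), ci("TCP")),
    tyrosination = divide(times(ci("Vm2"), ci("TubDetyr")),
                          plus(ci("Km2"), ci("TubDetyr"))),
    stop("no kinetic law template for reaction ", r$name))
}

#' Export the model as SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document with the six species (initial
#' concentrations from `init`; the TTL and TCP enzymes marked constant), the
#' nine kinetic parameters, and the six reactions with their rate laws as
#' MathML and the enzymes attached as modifiers.
#'
#' @param network a [cdt_network()].
#' @param params a [cdt_params()].
#' @param init a [cdt_initial_state()].
#' @param path output file.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' export_sbml(cdt_network(), cdt_params("neuronal"), cdt_initial_state(), f)
#' @export
export_sbml <- function(network, params, init, path) {
  sp <- vapply(network$species, function(s) sprintf(
    '<species id="%s" compartment="cell" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="%s"/>',
    s, as.numeric(init[s]),
    if (s %in% c("TTL", "TCP")) "true" else "false",
    if (s %in% c("TTL", "TCP")) "true" else "false"), "")
  pars <- vapply(CDT_PARAM_NAMES, function(p) sprintf(
    '<parameter id="%s" value="%.17g" constant="true"/>',
    p, as.numeric(params[p])), "")
  rx <- vapply(network$reactions, function(r) {
    refs <- function(tag, v) if (!length(v)) "" else sprintf(
      "<listOf%ss>%s</listOf%ss>", tag,
      paste0(sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                     names(v), as.integer(v)), collapse = ""), tag)
    mods <- if (!length(r$modifiers)) "" else sprintf(
      "<listOfModifiers>%s</listOfModifiers>",
      paste0(sprintf('<modifierSpeciesReference species="%s"/>', r$modifiers),
             collapse = ""))
    sprintf(paste0(
      '<reaction id="%s" reversible="false">%s%s%s',
      '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">%s</math></kineticLaw>',
      '</reaction>'),
      r$name, refs("Reactant", r$reactants), refs("Product", r$products),
      mods, sbml_rate_mathml(r))
  }, "")
  doc_text <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="detyrosination_tyrosination_cycle" name="Microtubule detyrosination/tyrosination cycle">',
    '<listOfCompartments><compartment id="cell" spatialDimensions="3" size="1" constant="true"/></listOfCompartments>',
    "<listOfSpecies>", paste0(sp, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste0(pars, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste0(rx, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  doc <- xml2::read_xml(doc_text)   # validates well-formedness
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an SBML model written by [export_sbml()]
#'
#' Recovers species with initial concentrations, parameter values, reaction
#' structure (stoichiometry matrix) and the kinetic laws as evaluable R
#' functions of `(state, params)` parsed from the MathML.
#'
#' @param path SBML file.
#' @return A list with `species`, `initial`, `params`, `reactions` (each with
#'   `name`, `reactants`, `products`, `modifiers`, `rate`), and
#'   `stoichiometry`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- xml2::xml_attr(sp_nodes, "id")
  initial <- setNames(as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")),
                      species)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  params <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                     xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    get_refs <- function(xp) {
      refs <- xml2::xml_find_all(node, xp)
      setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               xml2::xml_attr(refs, "species"))
    }
    math <- xml2::xml_find_first(node, ".//kineticLaw/math/*")
    expr <- mathml_to_expr(math)
    rate <- function(s, p) eval(expr, envir = as.list(c(s, p)))
    list(name = xml2::xml_attr(node, "id"),
         reactants = get_refs(".//listOfReactants/speciesReference"),
         products = get_refs(".//listOfProducts/speciesReference"),
         modifiers = xml2::xml_attr(
           xml2::xml_find_all(node, ".//listOfModifiers/modifierSpeciesReference"),
           "species"),
         kind = NA_character_, rate = rate)
  })
  stoich <- matrix(0, length(species), length(reactions),
                   dimnames = list(species,
                                   vapply(reactions, `[[`, "", "name")))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (length(r$reactants))
      stoich[names(r$reactants), j] <- stoich[names(r$reactants), j] - r$reactants
    if (length(r$products))
      stoich[names(r$products), j] <- stoich[names(r$products), j] + r$products
  }
  list(species = species, initial = initial, params = params,
       reactions = reactions, stoichiometry = stoich)
}

# converts the MathML subset used in kinetic laws (apply over times, divide,
# plus, minus, power; ci; cn) into an R expression
mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (name != "apply") stop("unsupported MathML node: ", name)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_expr)
  fn <- switch(op, times = "*", divide = "/", plus = "+", minus = "-",
               power = "^", stop("unsupported MathML operator: ", op))
  Reduce(function(a, b) call(fn, a, b), args)
}
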