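#' The six-reaction network of the detyrosination/tyrosination cycle
#'
#' Builds the chemical reaction network underlying the ODE model: two
#' polymerization reactions (mass action), two microtubule depolymerization
#' reactions (saturating kinetics), the detyrosination of tyrosinated
#' microtubules catalysed by TCP (mass action in the enzyme), and the
#' re-tyrosination of soluble detyrosinated tubulin catalysed by TTL
#' (saturating).  Every reaction converts one tubulin form into another, so
#' total tubulin is conserved; TTL and TCP are pure modifiers.
#'
#' @return An object of class `"cdt_network"`: a list with `species`,
#'   `reactions` (each a list with `name`, `reactants`, `products`,
#'   `modifiers`, `kind` of rate law, `rate` function of `(state, params)`),
#'   and the `stoichiometry` matrix (species x reactions).
#' @examples
#' net <- cdt_network()
#' net$stoichiometry
#' @export
cdt_network <- function() {
  reactions <- list(
    list(name = "polym_detyr", reactants = c(TubDetyr = 1), products = c(MTDetyr = 1),
         modifiers = character(), kind = "mass-action",
         rate = function(s, p) p[["kp1"]] * s[["TubDetyr"]]),
    list(name = "polym_tyr", reactants = c(TubTyr = 1), products = c(MTTyr = 1),
         modifiers = character(), kind = "mass-action",
         rate = function(s, p) p[["kp2"]] * s[["TubTyr"]]),
    list(name = "depolym_detyr", reactants = c(MTDetyr = 1), products = c(TubDetyr = 1),
         modifiers = character(), kind = "saturating",
         rate = function(s, p) p[["km1"]] * s[["MTDetyr"]] / (p[["mc1"]] + s[["MTDetyr"]])),
    list(name = "depolym_tyr", reactants = c(MTTyr = 1), products = c(TubTyr = 1),
         modifiers = character(), kind = "saturating",
         rate = function(s, p) p[["km2"]] * s[["MTTyr"]] / (p[["mc2"]] + s[["MTTyr"]])),
    list(name = "detyrosination", reactants = c(MTTyr = 1), products = c(MTDetyr = 1),
         modifiers = "TCP", kind = "mass-action",
         rate = function(s, p) p[["k1"]] * s[["MTTyr"]] * s[["TCP"]]),
    list(name = "tyrosination", reactants = c(TubDetyr = 1), products = c(TubTyr = 1),
         modifiers = "TTL", kind = "saturating",
         rate = function(s, p) p[["Vm2"]] * s[["TubDetyr"]] / (p[["Km2"]] + s[["TubDetyr"]]))
  )
  stoich <- matrix(0, nrow = length(CDT_SPECIES), ncol = length(reactions),
                   dimnames = list(CDT_SPECIES, vapply(reactions, `[[`, "", "name")))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    stoich[names(r$reactants), j] <- stoich[names(r$reactants), j] - r$reactants
    stoich[names(r$products), j] <- stoich[names(r$products), j] + r$products
  }
  structure(list(species = CDT_SPECIES, reactions = reactions,
                 stoichiometry = stoich),
            class = "cdt_network")
}

#' @export
print.cdt_network <- function(x, ...) {
  cat("Detyrosination/tyrosination cycle reaction network:",
      length(x$reactions), "reactions,", length(x$species), "species\n")
  for (r in x$reactions) {
    mods <- if (length(r$modifiers)) paste0(" [", paste(r$modifiers, collapse = ","), "]") else ""
    cat(sprintf("  %-15s %s -> %s%s (%s)\n", r$name,
                paste(names(r$reactants), collapse = "+"),
                paste(names(r$products), collapse = "+"), mods, r$kind))
  }
  invisible(x)
}

#' Network-derived right-hand side
#'
#' Computes the state derivative as stoichiometry matrix times flux vector.
#' This is an independent encoding of the same dynamics as [cdt_rhs()] (which
#' implements the balance equations directly); the two must agree to machine
#' precision and are cross-checked in the test suite.
#'
#' @param network a [cdt_network()].
#' @param state named concentrations (uM).
#' @param params a [cdt_params()] vector.
#' @return Named derivative vector in species order.
#' @export
network_rhs <- function(network, state, params) {
  s <- pmax(as.numeric(state[network$species]), 0)
  names(s) <- network$species
  flux <- vapply(network$reactions, function(r) r$rate(s, params), numeric(1))
  setNames(as.numeric(network$stoichiometry %*% flux), network$species)
}

#' Reaction fluxes at a state
#' @noRd
network_fluxes <- function(network, state, params) {
  s <- pmax(as.numeric(state[network$species]), 0)
  names(s) <- network$species
  setNames(vapply(network$reactions, function(r) r$rate(s, params), numeric(1)),
           vapply(network$reactions, `[[`, "", "name"))
}
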