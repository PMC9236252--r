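#' @useDynLib tyrcycle, .registration = TRUE
#' @importFrom stats rnorm runif rexp sd setNames approx uniroot
#' @importFrom utils write.csv read.csv modifyList
"_PACKAGE"

# canonical orderings used throughout the package; serialization is by name
CDT_SPECIES <- c("TubTyr", "TubDetyr", "MTDetyr", "MTTyr", "TTL", "TCP")
CDT_TUBULIN <- c("TubTyr", "TubDetyr", "MTDetyr", "MTTyr")
CDT_PARAM_NAMES <- c("kp1", "kp2", "km1", "mc1", "km2", "mc2", "k1", "Vm2", "Km2")

#' Kinetic parameters of the detyrosination/tyrosination cycle
#'
#' Returns the rate constants of the six-reaction cycle model for one of the
#' two reference parameterizations: `"neuronal"` (CDT_N, kinetic values taken
#' from the literature) or `"proliferative"` (CDT_P, identical except for the
#' detyrosinated-microtubule depolymerization rate `km1` and the maximal
#' tyrosination velocity `Vm2`, which are larger by factors of about 24.6 and
#' 38.5 respectively).  Individual values can be overridden through `...`,
#' which switches the variant tag to `"custom"` unless the overrides reproduce
#' a named variant exactly.
#'
#' Parameters (units as conventionally tabulated): `kp1`, `kp2` polymerization
#' rate constants (uM^-1 min^-1); `km1`, `km2` maximal depolymerization rates
#' (min^-1) with Michaelis constants `mc1`, `mc2` (uM); `k1` detyrosination
#' rate constant (mass action with the TCP concentration); `Vm2` maximal
#' tyrosination velocity (min^-1) with Michaelis constant `Km2` (uM).
#'
#' @param variant `"neuronal"`, `"proliferative"`, or `"custom"` (requires all
#'   nine values via `...`).
#' @param ... named numeric overrides of individual rate constants.
#' @return A named numeric vector of class `"cdt_params"` with attribute
#'   `variant`.
#' @examples
#' cdt_params("neuronal")
#' cdt_params("neuronal", km1 = 11.74, Vm2 = 7.70) # equals the proliferative set
#' @export
cdt_params <- function(variant = c("neuronal", "proliferative", "custom"), ...) {
  variant <- match.arg(variant)
  neuronal <- c(kp1 = 0.975, kp2 = 0.975, km1 = 0.478, mc1 = 2.75,
                km2 = 4.78, mc2 = 0.48, k1 = 1, Vm2 = 0.2, Km2 = 1.9)
  p <- switch(variant,
    neuronal = neuronal,
    proliferative = replace(neuronal, c("km1", "Vm2"), c(11.74, 7.70)),
    custom = neuronal)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), CDT_PARAM_NAMES)
    if (length(bad))
      stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(unlist(dots))
    variant <- classify_variant(p)
  }
  validate_params(p)
  structure(p[CDT_PARAM_NAMES], class = "cdt_params", variant = variant)
}

classify_variant <- function(p) {
  for (v in c("neuronal", "proliferative")) {
    ref <- cdt_params(v)
    if (isTRUE(all.equal(as.numeric(p[CDT_PARAM_NAMES]),
                         as.numeric(ref[CDT_PARAM_NAMES]), tolerance = 1e-12)))
      return(v)
  }
  "custom"
}

validate_params <- function(p) {
  if (!all(CDT_PARAM_NAMES %in% names(p)))
    stop("missing kinetic parameter(s): ",
         paste(setdiff(CDT_PARAM_NAMES, names(p)), collapse = ", "))
  if (any(!is.finite(p[CDT_PARAM_NAMES])))
    stop("kinetic parameters must be finite")
  # Michaelis constants appear in denominators and must stay strictly
  # positive; rate constants may hit 0 during scans and perturbations
  # (e.g. km1/Vm2 sweeps from 0, k1 dose-response down to full inhibition)
  strict <- c("mc1", "mc2", "Km2")
  if (any(p[strict] <= 0))
    stop("kinetic parameter(s) must be > 0: ",
         paste(strict[p[strict] <= 0], collapse = ", "))
  rates <- setdiff(CDT_PARAM_NAMES, strict)
  if (any(p[rates] < 0))
    stop("rate constant(s) must be >= 0: ",
         paste(rates[p[rates] < 0], collapse = ", "))
  invisible(p)
}

#' @export
print.cdt_params <- function(x, ...) {
  cat("Detyrosination/tyrosination cycle kinetic parameters (",
      attr(x, "variant"), " variant)\n", sep = "")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Initial concentrations of the cycle species
#'
#' The standard initial condition of the model: 5 uM tyrosinated soluble
#' tubulin, no other tubulin pools, and 1 uM each of the TTL and TCP enzymes.
#' Starting from an all-tyrosinated soluble pool mirrors in-vitro
#' detyrosination time courses in which only tyrosinated species are present
#' at time zero.  Because the cycle has a unique stable equilibrium (see
#' [check_multistability()]), redistributing the 5 uM of tubulin over the four
#' pools does not change the equilibrium.
#'
#' @param TubTyr,TubDetyr,MTDetyr,MTTyr,TTL,TCP concentrations in uM.
#' @return A named numeric vector of class `"cdt_state"` over the six species
#'   `TubTyr, TubDetyr, MTDetyr, MTTyr, TTL, TCP`.
#' @examples
#' cdt_initial_state()
#' @export
cdt_initial_state <- function(TubTyr = 5, TubDetyr = 0, MTDetyr = 0,
                              MTTyr = 0, TTL = 1, TCP = 1) {
  s <- c(TubTyr = TubTyr, TubDetyr = TubDetyr, MTDetyr = MTDetyr,
         MTTyr = MTTyr, TTL = TTL, TCP = TCP)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all concentrations must be finite and >= 0")
  structure(s, class = "cdt_state")
}

as_cdt_state <- function(x) {
  if (!all(CDT_SPECIES %in% names(x)))
    stop("state must name all species: ", paste(CDT_SPECIES, collapse = ", "))
  structure(as.numeric(x[CDT_SPECIES]), names = CDT_SPECIES, class = "cdt_state")
}

#' Time derivatives of the cycle species
#'
#' Evaluates the four tubulin/microtubule balance equations of the model (the
#' TTL and TCP enzymes are inert, so their derivatives are zero):
#' depolymerization of each microtubule pool follows saturating
#' (Michaelis-Menten) kinetics `km * MT / (mc + MT)`, polymerization is mass
#' action `kp * Tub`, detyrosination of tyrosinated microtubules is mass
#' action in the TCP concentration, `k1 * MTTyr * TCP`, and re-tyrosination of
#' soluble detyrosinated tubulin by TTL is saturating,
#' `Vm2 * TubDetyr / (Km2 + TubDetyr)`.
#'
#' Negative concentrations (possible transiently from integrator overshoot)
#' are clipped to zero before flux evaluation.
#'
#' @param state named concentrations over the six species (uM).
#' @param params a [cdt_params()] vector.
#' @return Named numeric vector of derivatives (uM/min) in species order.
#' @examples
#' cdt_rhs(cdt_initial_state(), cdt_params("neuronal"))
#' @export
cdt_rhs <- function(state, params) {
  s <- pmax(as.numeric(state[CDT_SPECIES]), 0)
  names(s) <- CDT_SPECIES
  p <- as.numeric(params[CDT_PARAM_NAMES])
  names(p) <- CDT_PARAM_NAMES

  depol_detyr <- p["km1"] * s["MTDetyr"] / (p["mc1"] + s["MTDetyr"])
  depol_tyr <- p["km2"] * s["MTTyr"] / (p["mc2"] + s["MTTyr"])
  detyr_flux <- p["k1"] * s["MTTyr"] * s["TCP"]
  tyr_flux <- p["Vm2"] * s["TubDetyr"] / (p["Km2"] + s["TubDetyr"])

  unname_all(c(
    TubTyr = depol_tyr - p["kp2"] * s["TubTyr"] + tyr_flux,
    TubDetyr = depol_detyr - p["kp1"] * s["TubDetyr"] - tyr_flux,
    MTDetyr = p["kp1"] * s["TubDetyr"] - depol_detyr + detyr_flux,
    MTTyr = p["kp2"] * s["TubTyr"] - depol_tyr - detyr_flux,
    TTL = 0, TCP = 0))
}

# c(TubTyr = x["a"]) produces names like "TubTyr.a"; strip and reapply
unname_all <- function(x) setNames(as.numeric(x), CDT_SPECIES)

#' Aggregate tyrosination observables of a state
#'
#' `Tyr` is the total tyrosinated pool (soluble + polymerized), `Detyr` the
#' total detyrosinated pool, and `TyrDetyr = Tyr/Detyr` the tyrosination
#' status, the model's central readout.  When the detyrosinated pool is below
#' `1e-12` uM the ratio is reported as `Inf`.
#'
#' @param state named concentrations over the six species (uM).
#' @return Named numeric vector `c(Tyr, Detyr, TyrDetyr)`.
#' @examples
#' observables(cdt_initial_state())
#' @export
observables <- function(state) {
  tyr <- unname(state["TubTyr"] + state["MTTyr"])
  detyr <- unname(state["TubDetyr"] + state["MTDetyr"])
  c(Tyr = tyr, Detyr = detyr,
    TyrDetyr = if (detyr < 1e-12) Inf else tyr / detyr)
}
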