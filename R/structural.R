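# Structural multistationarity analysis.
#
# A necessary condition for multiple non-degenerate steady states of the ODE
# semantics is the existence of a positive circuit in the labelled influence
# graph of the reaction network.  Arcs record which species accelerate or
# decelerate the production of which other species, labelled by the reaction
# responsible.  A positive circuit only witnesses possible multistationarity
# if its arcs come from pairwise-distinct reactions AND the square
# stoichiometric submatrix (circuit species x circuit reactions) is
# nonsingular; pure conversion loops (A -> B -> A through two reactions that
# shuffle the same mass back and forth) have singular submatrices and are
# discarded.  With no admissible positive circuit, the equilibrium reached
# from any initial condition is unique.

#' Labelled influence graph of a reaction network
#'
#' An arc `(source, target, sign, reaction)` is drawn whenever `source`
#' affects the rate of `reaction` and `reaction` changes `target`; the sign
#' is the sign of the stoichiometric change of `target` times the sign of the
#' rate dependence on `source`.  Dependence is established on the actual rate
#' law, not the declared reactant/modifier lists, so a modifier that does not
#' appear in the implemented kinetics (the TTL enzyme, whose saturating
#' tyrosination law carries its activity inside `Vm2`) generates no arcs.
#'
#' @param network a [cdt_network()] (or any object of the same shape).
#' @return A data frame of class `"cdt_influence"` with columns `source`,
#'   `target`, `sign` (+1/-1), `reaction`.
#' @examples
#' influence_graph(cdt_network())
#' @export
influence_graph <- function(network) {
  arcs <- NULL
  S <- network$stoichiometry
  probe <- setNames(rep(1, length(network$species)), network$species)
  p_probe <- cdt_params("neuronal")
  rate_dep_sign <- function(rate, src) {
    hi <- probe; hi[src] <- 2
    d <- rate(hi, p_probe) - rate(probe, p_probe)
    if (abs(d) < 1e-12) 0 else sign(d)
  }
  for (r in network$reactions) {
    candidates <- unique(c(names(r$reactants), r$modifiers))
    targets <- rownames(S)[S[, r$name] != 0]
    for (src in candidates) {
      dep <- rate_dep_sign(r$rate, src)
      if (dep == 0) next
      for (tgt in targets)
        arcs <- rbind(arcs, data.frame(source = src, target = tgt,
                                       sign = dep * sign(S[tgt, r$name]),
                                       reaction = r$name))
    }
  }
  if (is.null(arcs))
    arcs <- data.frame(source = character(), target = character(),
                       sign = numeric(), reaction = character())
  structure(arcs, class = c("cdt_influence", "data.frame"))
}

#' Admissible positive circuits of the influence graph
#'
#' Enumerates every simple circuit of the labelled influence multigraph (node
#' sequences without repetition, one arc chosen per step, arcs carrying
#' pairwise-distinct reaction labels), keeps those whose sign product is
#' positive, and retains only the admissible ones: circuits whose square
#' stoichiometric submatrix over (circuit species, circuit reactions) is
#' nonsingular.  For the cycle network the list is empty — all positive
#' sign-loops are mass-conserving conversion loops with singular submatrices.
#'
#' @param graph a `"cdt_influence"` data frame.
#' @param network the generating network (for the stoichiometry matrix).
#' @return A list of circuits; each has `species`, `reactions`, `signs`,
#'   and `determinant`.
#' @export
admissible_positive_circuits <- function(graph, network) {
  keep <- lapply(enumerate_circuits(graph), function(circ) {
    if (prod(circ$signs) <= 0) return(NULL)
    if (anyDuplicated(circ$reactions)) return(NULL)
    sub <- network$stoichiometry[circ$species, circ$reactions, drop = FALSE]
    d <- det(sub)
    if (abs(d) < 1e-12) return(NULL)
    c(circ, list(determinant = d))
  })
  Filter(Negate(is.null), keep)
}

# all simple circuits of the labelled multigraph: DFS from each node (with a
# canonical smallest-start restriction so each circuit is found once), taking
# every parallel arc variant
enumerate_circuits <- function(graph) {
  if (!nrow(graph)) return(list())
  nodes <- sort(unique(c(graph$source, graph$target)))
  out <- list()
  arcs_from <- split(seq_len(nrow(graph)), graph$source)

  extend <- function(path_nodes, path_arcs, start) {
    last <- path_nodes[length(path_nodes)]
    for (i in arcs_from[[last]]) {
      tgt <- graph$target[i]
      if (tgt == start) {
        out[[length(out) + 1L]] <<- list(
          species = path_nodes,
          reactions = graph$reaction[c(path_arcs, i)],
          signs = graph$sign[c(path_arcs, i)])
      } else if (!(tgt %in% path_nodes) && tgt > start) {
        # only visit nodes "larger" than the start so each circuit is
        # enumerated exactly once (from its smallest node)
        extend(c(path_nodes, tgt), c(path_arcs, i), start)
      }
    }
  }
  for (v in nodes) if (!is.null(arcs_from[[v]])) extend(v, integer(), v)
  out
}

#' Structural check for multistationarity
#'
#' Returns `"unique-steady-state-guaranteed"` when the influence graph of the
#' network contains no admissible positive circuit (a necessary condition for
#' multiple non-degenerate steady states fails, so the equilibrium of the ODE
#' system is unique); otherwise `"inconclusive"`, with the circuits as
#' evidence.
#'
#' @param network a [cdt_network()].
#' @return A list of class `"cdt_multistability"` with `verdict` and
#'   `evidence` (the admissible positive circuits, possibly empty).
#' @examples
#' check_multistability(cdt_network())$verdict
#' @export
check_multistability <- function(network) {
  g <- influence_graph(network)
  circuits <- admissible_positive_circuits(g, network)
  structure(list(verdict = if (length(circuits))
                   "inconclusive" else "unique-steady-state-guaranteed",
                 evidence = circuits),
            class = "cdt_multistability")
}

#' @export
print.cdt_multistability <- function(x, ...) {
  cat("Multistationarity check:", x$verdict, "\n")
  if (length(x$evidence)) {
    cat("admissible positive circuits:\n")
    for (c0 in x$evidence)
      cat("  ", paste(c0$species, collapse = " -> "), " via ",
          paste(c0$reactions, collapse = ", "), "\n", sep = "")
  } else {
    cat("no admissible positive circuit in the influence graph\n")
  }
  invisible(x)
}

#' Numerical cross-check of equilibrium uniqueness
#'
#' Samples `n_starts` random initial states uniformly on the simplex of the
#' conserved total tubulin (default 5 uM split over the four tubulin pools,
#' enzymes at 1 uM), simulates each to steady state, and checks that all
#' final states agree componentwise within `tol`.
#'
#' @param params a [cdt_params()] vector.
#' @param n_starts number of random initial conditions (>= 2).
#' @param seed integer seed.
#' @param total conserved tubulin total in uM.
#' @param tol componentwise agreement tolerance in uM.
#' @param horizon steady-state horizon in minutes.
#' @return `TRUE` if every start converged to the same state; errors if any
#'   run failed to stabilize.
#' @examples
#' \donttest{
#' numerical_uniqueness_check(cdt_params("neuronal"), n_starts = 5, seed = 1)
#' }
#' @export
numerical_uniqueness_check <- function(params, n_starts = 20, seed = 1,
                                       total = 5, tol = 1e-4,
                                       horizon = 10000) {
  if (n_starts < 2) stop("n_starts must be >= 2")
  splits <- with_local_seed(seed, {
    m <- matrix(rexp(4 * n_starts), ncol = 4)
    m / rowSums(m) * total
  })
  finals <- matrix(NA_real_, n_starts, length(CDT_SPECIES),
                   dimnames = list(NULL, CDT_SPECIES))
  for (i in seq_len(n_starts)) {
    init <- cdt_initial_state(TubTyr = splits[i, 1], TubDetyr = splits[i, 2],
                              MTDetyr = splits[i, 3], MTTyr = splits[i, 4])
    res <- simulate_to_steady(params, init, horizon = horizon)
    if (!res$steady$converged)
      stop("start ", i, " did not stabilize within ", horizon, " min")
    finals[i, ] <- as.numeric(res$steady$state)
  }
  spread <- apply(finals, 2, function(col) diff(range(col)))
  all(spread < tol)
}
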