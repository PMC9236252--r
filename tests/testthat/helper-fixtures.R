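# Shared fixtures: synthetic traces with prescribed dynamics and small toy
# networks for the structural analysis, all built in code.

# a cdt_trace-shaped object with prescribed species columns (functions of
# time or constants), carrying the usual observables and a parameter schedule
make_synthetic_trace <- function(times, species_fns,
                                 params = cdt_params("neuronal")) {
  cols <- lapply(c("TubTyr", "TubDetyr", "MTDetyr", "MTTyr", "TTL", "TCP"),
                 function(sp) {
    fn <- species_fns[[sp]]
    if (is.null(fn)) rep(0, length(times))
    else if (is.function(fn)) fn(times)
    else rep(fn, length(times))
  })
  tr <- data.frame(Time = times)
  tr[c("TubTyr", "TubDetyr", "MTDetyr", "MTTyr", "TTL", "TCP")] <- cols
  tyr <- tr$TubTyr + tr$MTTyr
  detyr <- tr$TubDetyr + tr$MTDetyr
  tr$Tyr <- tyr
  tr$Detyr <- detyr
  tr$TyrDetyr <- ifelse(detyr < 1e-12, Inf, tyr / detyr)
  schedule <- data.frame(from = 0, t(as.numeric(params)))
  names(schedule) <- c("from", names(unclass(params)))
  structure(tr, class = c("cdt_trace", "data.frame"),
            params = params, events = list(), schedule = schedule)
}

# minimal network object: reactions as (reactants, products, modifiers, rate)
make_toy_network <- function(species, reactions) {
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
  structure(list(species = species, reactions = reactions,
                 stoichiometry = stoich),
            class = "cdt_network")
}

# independent brute-force circuit oracle: tries every node subset and
# ordering, every arc choice per step (labels pairwise distinct)
brute_force_circuits <- function(graph) {
  nodes <- sort(unique(c(graph$source, graph$target)))
  out <- list()
  arcs_between <- function(a, b)
    which(graph$source == a & graph$target == b)
  build <- function(seq_nodes) {
    n <- length(seq_nodes)
    steps <- lapply(seq_len(n), function(i)
      arcs_between(seq_nodes[i], seq_nodes[i %% n + 1]))
    if (any(lengths(steps) == 0)) return()
    combos <- expand.grid(steps)
    for (k in seq_len(nrow(combos))) {
      idx <- as.integer(combos[k, ])
      if (anyDuplicated(graph$reaction[idx])) next
      out[[length(out) + 1L]] <<- list(species = seq_nodes,
                                       reactions = graph$reaction[idx],
                                       signs = graph$sign[idx])
    }
  }
  subsets <- function(v) {
    if (!length(v)) return(list(character()))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (sub in subsets(nodes)) {
    if (!length(sub)) next
    anchor <- sub[1]  # canonical: cycles start at their smallest node
    others <- sub[-1]
    perms <- if (!length(others)) list(character()) else all_perms(others)
    for (p in perms) build(c(anchor, p))
  }
  out
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# canonical string form of a circuit for set comparison
circuit_key <- function(circ) {
  n <- length(circ$species)
  rot <- which(circ$species == min(circ$species))[1]
  idx <- ((seq_len(n) + rot - 2) %% n) + 1
  paste(paste(circ$species[idx], collapse = ">"),
        paste(circ$reactions[idx], collapse = ">"), sep = "|")
}

# A <-> B conversion pair: a positive sign-loop whose stoichiometric
# submatrix is singular (pure mass shuffling)
toy_conversion <- function() {
  make_toy_network(c("A", "B"), list(
    list(name = "fwd", reactants = c(A = 1), products = c(B = 1),
         modifiers = character(), kind = "mass-action",
         rate = function(s, p) s[["A"]]),
    list(name = "rev", reactants = c(B = 1), products = c(A = 1),
         modifiers = character(), kind = "mass-action",
         rate = function(s, p) s[["B"]])))
}

# X catalyzes production of Y from a source and vice versa: an admissible
# positive circuit (diagonal stoichiometric submatrix)
toy_mutual_activation <- function() {
  make_toy_network(c("X", "Y"), list(
    list(name = "prod_Y", reactants = c(), products = c(Y = 1),
         modifiers = "X", kind = "mass-action",
         rate = function(s, p) s[["X"]]),
    list(name = "prod_X", reactants = c(), products = c(X = 1),
         modifiers = "Y", kind = "mass-action",
         rate = function(s, p) s[["Y"]])))
}
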