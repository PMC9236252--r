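#' Parse a temporal-logic behavioural specification
#'
#' Parses the plain-text mini-language used to state behavioural constraints
#' on simulation traces, e.g.
#'
#' ```
#' F(Time == 5 /\ Tyr = factor1 * Detyr /\ F(Time == 20 /\ Tyr = factor2 * Detyr))
#' F(G(TyrDetyr = x))
#' F(Time == 5 /\ Tyr = factor1)
#' ```
#'
#' Supported constructs: `F(...)` (eventually), `G(...)` (always), conjunction
#' `/\`, and atomic linear constraints `Time == t`, `V = var`,
#' `V = var * W`, and `V = c`, where `V`, `W` are observables, species, or
#' kinetic parameters visible on a trace, `var` is a free variable and `c`,
#' `t` are numeric constants.  The nesting patterns supported are those needed
#' for behavioural fitting: `F(conj)`, `F(conj /\ F(conj))`, and `F(G(conj))`.
#' Each free variable must occur exactly once.
#'
#' @param text the formula as a character string.
#' @return An object of class `"tl_formula"` (an abstract syntax tree) with
#'   attributes `free_vars` and `text`.
#' @examples
#' f <- parse_formula("F(Time == 5 /\\ Tyr = factor1)")
#' attr(f, "free_vars")
#' @export
parse_formula <- function(text) {
  toks <- tl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- tl_parse_temporal(st)
  if (st$pos <= length(st$toks))
    stop("trailing input after formula: ", st$toks[st$pos])
  vars <- tl_free_vars(node)
  if (anyDuplicated(vars))
    stop("free variable(s) occur more than once: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  structure(node, class = "tl_formula", free_vars = vars, text = text)
}

tl_tokenize <- function(text) {
  pat <- "/\\\\|==|=|\\*|\\(|\\)|[A-Za-z_][A-Za-z0-9_]*|[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  rest <- gsub(pat, "", text)
  if (grepl("[^ \t\n]", rest))
    stop("unexpected character(s) in formula: ",
         gsub("[ \t\n]", "", rest))
  toks
}

tl_peek <- function(st, k = 0) {
  i <- st$pos + k
  if (i > length(st$toks)) "" else st$toks[i]
}

tl_take <- function(st, expected = NULL) {
  tok <- tl_peek(st)
  if (tok == "") stop("unexpected end of formula")
  if (!is.null(expected) && tok != expected)
    stop("expected '", expected, "' but found '", tok, "'")
  st$pos <- st$pos + 1L
  tok
}

tl_is_number <- function(tok) grepl("^[0-9.]", tok)

tl_parse_temporal <- function(st) {
  op <- tl_take(st)
  if (!op %in% c("F", "G")) stop("expected F(...) or G(...), found '", op, "'")
  tl_take(st, "(")
  body <- tl_parse_conj(st)
  tl_take(st, ")")
  if (op == "G" && !is.null(body$nested))
    stop("nested temporal operators inside G(...) are not supported")
  list(op = op, atoms = body$atoms, nested = body$nested)
}

tl_parse_conj <- function(st) {
  atoms <- list()
  nested <- NULL
  repeat {
    if (tl_peek(st) %in% c("F", "G") && tl_peek(st, 1) == "(") {
      if (!is.null(nested)) stop("at most one nested temporal operator per conjunction")
      nested <- tl_parse_temporal(st)
    } else {
      atoms[[length(atoms) + 1L]] <- tl_parse_atom(st)
    }
    if (tl_peek(st) == "/\\") tl_take(st) else break
  }
  list(atoms = atoms, nested = nested)
}

tl_parse_atom <- function(st) {
  lhs <- tl_take(st)
  if (tl_is_number(lhs)) stop("atom must start with an identifier, found '", lhs, "'")
  op <- tl_take(st)
  if (op == "==") {
    rhs <- tl_take(st)
    if (lhs == "Time") {
      if (!tl_is_number(rhs)) stop("Time == requires a numeric constant")
      return(list(kind = "time", t = as.numeric(rhs)))
    }
    if (!tl_is_number(rhs)) stop("'==' requires a numeric right-hand side")
    return(list(kind = "const", lhs = lhs, value = as.numeric(rhs)))
  }
  if (op != "=") stop("expected '=' or '==' after '", lhs, "'")
  rhs <- tl_take(st)
  if (tl_is_number(rhs))
    return(list(kind = "const", lhs = lhs, value = as.numeric(rhs)))
  if (tl_peek(st) == "*") {
    tl_take(st)
    w <- tl_take(st)
    if (tl_is_number(w)) stop("ratio atom requires an identifier after '*'")
    return(list(kind = "bind", lhs = lhs, var = rhs, mult = w))
  }
  list(kind = "bind", lhs = lhs, var = rhs, mult = NULL)
}

tl_free_vars <- function(node) {
  vars <- character()
  for (a in node$atoms) if (a$kind == "bind") vars <- c(vars, a$var)
  if (!is.null(node$nested)) vars <- c(vars, tl_free_vars(node$nested))
  vars
}

#' Times at which a formula constrains the trace
#' @param formula a parsed `"tl_formula"`.
#' @return Numeric vector of the `Time ==` anchor values (possibly empty).
#' @export
formula_times <- function(formula) {
  times <- numeric()
  walk <- function(node) {
    for (a in node$atoms) if (a$kind == "time") times <<- c(times, a$t)
    if (!is.null(node$nested)) walk(node$nested)
  }
  walk(formula)
  sort(unique(times))
}

formula_has_G <- function(formula) {
  walk <- function(node) node$op == "G" ||
    (!is.null(node$nested) && walk(node$nested))
  walk(formula)
}

#' @export
print.tl_formula <- function(x, ...) {
  cat("Temporal formula:", attr(x, "text"), "\n")
  if (length(attr(x, "free_vars")))
    cat("  free variables:", paste(attr(x, "free_vars"), collapse = ", "), "\n")
  invisible(x)
}

# value of an identifier (observable, species, or kinetic parameter) on the
# trace at the grid point t
tl_value_at <- function(trace, name, t) {
  if (name %in% names(trace)) {
    i <- which(abs(trace$Time - t) < 1e-9)
    if (!length(i))
      stop("time ", t, " is not a report point of the trace")
    return(trace[[name]][i[1]])
  }
  if (name %in% CDT_PARAM_NAMES)
    return(as.numeric(params_at_time(trace, t)[name]))
  stop("'", name, "' is neither a trace observable nor a kinetic parameter")
}

tl_terminal_value <- function(trace, name) {
  if (name %in% names(trace)) return(trace[[name]][nrow(trace)])
  if (name %in% CDT_PARAM_NAMES)
    return(as.numeric(params_at_time(trace, max(trace$Time))[name]))
  stop("'", name, "' is neither a trace observable nor a kinetic parameter")
}

tl_window_mean <- function(trace, name, window) {
  if (name %in% CDT_PARAM_NAMES)
    return(as.numeric(params_at_time(trace, max(trace$Time))[name]))
  sel <- trace$Time >= max(trace$Time) - window
  mean(trace[[name]][sel & is.finite(trace[[name]])])
}

eval_bind_atom <- function(a, get) {
  v <- get(a$lhs)
  if (!is.null(a$mult)) {
    w <- get(a$mult)
    v <- if (abs(w) < 1e-12) Inf else v / w
  }
  setNames(v, a$var)
}

#' Free-variable values a trace can achieve for a formula
#'
#' Extracts the achievable free-variable assignments (validity points) of a
#' behavioural formula on a trace.  With exact `Time ==` anchoring each
#' supported formula has at most one validity point: `F(Time == t /\ V = var
#' /\ ...)` binds `var` to `V(t)` (a nested `F` is restricted to the suffix
#' after `t`); a ratio atom `V = var * W` binds `var` to `V(t)/W(t)`; for
#' `F(G(V = var))` the trace must have stabilized (see [steady_state()]) and
#' `var` is bound to the terminal value of `V`.
#'
#' @param formula a `"tl_formula"` (or a character string, parsed on the fly).
#' @param trace a `"cdt_trace"` containing every named observable and with
#'   report points at every `Time ==` anchor.
#' @param window,rel_tol stabilization criterion passed to [steady_state()]
#'   for the `F(G(...))` case.
#' @return A list with `points` (list of named numeric vectors; empty when a
#'   `G` sub-formula did not stabilize), `non_stabilized` flag, and
#'   `fallback` (terminal-window means of the `G`-bound observables, used by
#'   [satisfaction_degree()] when the trace did not stabilize).
#' @examples
#' tr <- simulate_cdt(cdt_params("neuronal"), horizon = 10,
#'                    report_times = 5, step = NA)
#' validity_points("F(Time == 5 /\\ Tyr = f1)", tr)$points
#' @export
validity_points <- function(formula, trace, window = 10, rel_tol = 1e-6) {
  if (is.character(formula)) formula <- parse_formula(formula)
  res <- tl_eval_node(formula, trace, t_min = 0, window = window,
                      rel_tol = rel_tol)
  # hard failures (constant atoms violated) surface as empty with no fallback
  res
}

tl_eval_node <- function(node, trace, t_min, window, rel_tol) {
  if (node$op == "F" && !is.null(node$nested) && node$nested$op == "G") {
    if (length(node$atoms)) stop("F(G(...)) may not carry additional atoms")
    return(tl_eval_FG(node$nested, trace, window, rel_tol))
  }
  time_atoms <- Filter(function(a) a$kind == "time", node$atoms)
  if (node$op != "F" || length(time_atoms) != 1)
    stop("unsupported formula pattern: each F(...) needs exactly one Time == anchor ",
         "(or a single nested G)")
  t <- time_atoms[[1]]$t
  if (t < t_min)
    stop("nested Time == ", t, " precedes its enclosing anchor at ", t_min)
  if (t > max(trace$Time))
    stop("Time == ", t, " lies outside the trace horizon ", max(trace$Time))
  get <- function(name) tl_value_at(trace, name, t)
  point <- numeric()
  for (a in node$atoms) {
    if (a$kind == "bind") point <- c(point, eval_bind_atom(a, get))
    if (a$kind == "const") {
      # constant atoms are hard constraints folded into the distance via a
      # pseudo-variable named after the constrained quantity
      point <- c(point, setNames(get(a$lhs), paste0(".const_", a$lhs)))
    }
  }
  non_stab <- FALSE
  fallback <- NULL
  if (!is.null(node$nested)) {
    inner <- tl_eval_node(node$nested, trace, t_min = t, window = window,
                          rel_tol = rel_tol)
    non_stab <- inner$non_stabilized
    fallback <- inner$fallback
    if (!length(inner$points))
      return(list(points = list(), non_stabilized = non_stab,
                  fallback = c(point, fallback)))
    point <- c(point, inner$points[[1]])
  }
  list(points = list(point), non_stabilized = non_stab, fallback = fallback)
}

tl_eval_FG <- function(gnode, trace, window, rel_tol) {
  st <- steady_state(trace, window = window, rel_tol = rel_tol)
  point <- numeric()
  get <- function(name) tl_terminal_value(trace, name)
  for (a in gnode$atoms) {
    if (a$kind == "bind") point <- c(point, eval_bind_atom(a, get))
    if (a$kind == "const")
      point <- c(point, setNames(get(a$lhs), paste0(".const_", a$lhs)))
  }
  if (!st$converged) {
    fb <- numeric()
    getm <- function(name) tl_window_mean(trace, name, window)
    for (a in gnode$atoms) {
      if (a$kind == "bind") fb <- c(fb, eval_bind_atom(a, getm))
      if (a$kind == "const")
        fb <- c(fb, setNames(getm(a$lhs), paste0(".const_", a$lhs)))
    }
    return(list(points = list(), non_stabilized = TRUE, fallback = fb))
  }
  list(points = list(point), non_stabilized = FALSE, fallback = NULL)
}

#' Continuous satisfaction degree of a formula on a trace
#'
#' Measures how close a trace comes to a behavioural specification.  The
#' violation degree is the Euclidean distance between the objective point and
#' the nearest validity point, with each coordinate scaled by
#' `max(|objective|, 1e-9)` (a relative error per free variable); the
#' satisfaction degree is `1 / (1 + violation)`, which equals 1 exactly when
#' the objectives are achievable and decreases continuously with distance.
#' On a trace that failed to stabilize, an `F(G(...))` formula is scored
#' against the terminal-window mean, so the degree is well defined but below
#' any stabilized competitor in practice.
#'
#' @param formula a `"tl_formula"` or character string.
#' @param trace a `"cdt_trace"`.
#' @param objectives named numeric vector or list mapping every free variable
#'   of the formula to its objective value.
#' @param window,rel_tol stabilization criterion for `G` sub-formulas.
#' @return A list of class `"tl_satisfaction"` with `validity_points`,
#'   `violation_degree`, `satisfaction_degree`, and `achieved` (the variable
#'   values the trace realized).
#' @examples
#' tr <- simulate_cdt(cdt_params("neuronal"), horizon = 10,
#'                    report_times = 5, step = NA)
#' satisfaction_degree("F(Time == 5 /\\ Tyr = f1)", tr, c(f1 = 2.5))
#' @export
satisfaction_degree <- function(formula, trace, objectives,
                                window = 10, rel_tol = 1e-6) {
  if (is.character(formula)) formula <- parse_formula(formula)
  objectives <- unlist(objectives)
  vars <- attr(formula, "free_vars")
  if (!setequal(names(objectives), vars))
    stop("objectives must cover exactly the free variables: ",
         paste(vars, collapse = ", "))
  vp <- validity_points(formula, trace, window = window, rel_tol = rel_tol)

  score_point <- function(point) {
    full_obj <- objectives
    # constant atoms score against their stated constants
    consts <- grep("^\\.const_", names(point), value = TRUE)
    if (length(consts)) {
      cv <- tl_const_targets(formula)
      full_obj <- c(full_obj, cv[consts])
    }
    d <- (point[names(full_obj)] - full_obj) / pmax(abs(full_obj), 1e-9)
    d[!is.finite(d)] <- 1e9   # Inf ratios count as maximally violated
    sqrt(sum(d^2))
  }

  if (length(vp$points)) {
    vd <- min(vapply(vp$points, score_point, numeric(1)))
    achieved <- vp$points[[1]]
  } else if (!is.null(vp$fallback)) {
    vd <- score_point(vp$fallback)
    achieved <- vp$fallback
  } else {
    vd <- Inf
    achieved <- NULL
  }
  structure(list(validity_points = vp$points,
                 violation_degree = vd,
                 satisfaction_degree = 1 / (1 + vd),
                 achieved = achieved,
                 non_stabilized = vp$non_stabilized),
            class = "tl_satisfaction")
}

tl_const_targets <- function(formula) {
  out <- numeric()
  walk <- function(node) {
    for (a in node$atoms) if (a$kind == "const")
      out[paste0(".const_", a$lhs)] <<- a$value
    if (!is.null(node$nested)) walk(node$nested)
  }
  walk(formula)
  out
}

#' @export
print.tl_satisfaction <- function(x, ...) {
  cat("satisfaction degree:", format(x$satisfaction_degree, digits = 6),
      "(violation", format(x$violation_degree, digits = 4), ")\n")
  if (!is.null(x$achieved)) {
    cat("achieved values:\n")
    print(x$achieved)
  }
  invisible(x)
}

#' Parse objective assignments written as `name -> value` pairs
#'
#' @param text e.g. `"factor1 -> 10, factor2 -> 10"`.
#' @return Named numeric vector.
#' @examples
#' parse_objectives("factor1 -> 10, factor2 -> 10")
#' @export
parse_objectives <- function(text) {
  parts <- strsplit(text, ",")[[1]]
  out <- numeric()
  for (p in parts) {
    kv <- strsplit(trimws(p), "->")[[1]]
    if (length(kv) != 2) stop("objective entries must be 'name -> value': ", p)
    out[trimws(kv[1])] <- as.numeric(trimws(kv[2]))
  }
  out
}
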