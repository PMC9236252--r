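#' Construct a timed parameter-change event
#'
#' Events model the addition of an activator or inhibitor compound during a
#' simulation: at the first report time at or after `time`, the named kinetic
#' parameters are reassigned.  With `mode = "absolute"` the assignment values
#' are the new parameter values; with `mode = "fold"` they multiply the value
#' in force at firing time (so stacked fold events compound).
#'
#' @param time trigger time in minutes, > 0.
#' @param ... named numeric assignments, e.g. `Vm2 = 2` or `k1 = 0.01`.
#' @param mode `"absolute"` or `"fold"`.
#' @return An object of class `"cdt_event"`.
#' @examples
#' cdt_event(60, Vm2 = 2)          # set Vm2 to 2 at t = 60
#' cdt_event(60, Vm2 = 10, mode = "fold")  # multiply Vm2 by 10 at t = 60
#' @export
cdt_event <- function(time, ..., mode = c("absolute", "fold")) {
  mode <- match.arg(mode)
  assignments <- unlist(list(...))
  if (!is.numeric(time) || length(time) != 1 || time <= 0)
    stop("event trigger time must be a single value > 0")
  if (!length(assignments) || is.null(names(assignments)) || any(names(assignments) == ""))
    stop("event assignments must be named")
  if (anyDuplicated(names(assignments)))
    stop("each parameter may be assigned at most once per event")
  bad <- setdiff(names(assignments), CDT_PARAM_NAMES)
  if (length(bad))
    stop("unknown kinetic parameter(s) in event: ", paste(bad, collapse = ", "))
  structure(list(time = time, assignments = assignments, mode = mode),
            class = "cdt_event")
}

#' Build the fold-change perturbation events used in the perturbed simulations
#'
#' Convenience constructor for the in-silico drug additions: multiply one or
#' more kinetic parameters by a common factor once the system has reached its
#' (near-)steady state.  The conventional trigger times are 20 min for the
#' proliferative model and 60 min for the neuronal model.  The returned event
#' carries absolute values resolved against `params`, e.g. a tenfold increase
#' of `Vm2` on the neuronal base yields `Vm2 = 2`.
#'
#' @param params a [cdt_params()] vector (or variant name) giving the baseline.
#' @param parameters character vector of parameter names to scale.
#' @param fold_change common multiplicative factor, > 0.
#' @param trigger_time event time in minutes.
#' @return A list containing one `"cdt_event"`.
#' @examples
#' perturbation_preset(cdt_params("neuronal"), c("km1", "Vm2"), 10, 60)
#' @export
perturbation_preset <- function(params, parameters, fold_change, trigger_time) {
  if (is.character(params) && is.null(attr(params, "variant")))
    params <- cdt_params(params)
  bad <- setdiff(parameters, CDT_PARAM_NAMES)
  if (length(bad))
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
  if (fold_change <= 0) stop("fold_change must be > 0")
  values <- as.numeric(params[parameters]) * fold_change
  ev <- do.call(cdt_event,
                c(list(time = trigger_time), as.list(setNames(values, parameters))))
  list(ev)
}

apply_event <- function(params, event) {
  p <- unclass(params)
  if (event$mode == "fold") {
    p[names(event$assignments)] <- p[names(event$assignments)] * event$assignments
  } else {
    p[names(event$assignments)] <- event$assignments
  }
  structure(p, class = "cdt_params", variant = classify_variant(p))
}

#' Simulate the cycle model
#'
#' Numerically integrates the model with `deSolve`'s stiff-capable adaptive
#' solver (`lsoda`, relative tolerance `1e-8`, absolute `1e-10` by default).
#' Timed parameter-change events are realized by splitting the integration
#' interval at each trigger time and restarting with updated parameters, so an
#' event fires exactly once, at its trigger time.  The compiled right-hand
#' side is used by default; `compiled = FALSE` integrates the pure-R
#' [cdt_rhs()] instead (same equations, used for cross-checking).
#'
#' @param params a [cdt_params()] vector.
#' @param init initial state, default [cdt_initial_state()].
#' @param horizon end time in minutes, > 0.
#' @param events list of [cdt_event()]s (any order; sorted internally).
#' @param report_times additional times to include in the output grid.
#' @param step regular grid spacing in minutes (default 0.1); `NA` to report
#'   only at `report_times` (plus 0, `horizon` and event times).
#' @param rtol,atol integrator tolerances.
#' @param compiled use the compiled right-hand side.
#' @return A `"cdt_trace"` data frame with columns `Time`, the six species,
#'   and the derived observables `Tyr`, `Detyr`, `TyrDetyr`.  The initial
#'   parameters, the events, and the per-segment parameter schedule are kept
#'   as attributes.
#' @examples
#' tr <- simulate_cdt(cdt_params("neuronal"), horizon = 60)
#' tail(tr[, c("Time", "Tyr", "Detyr", "TyrDetyr")], 3)
#' @export
simulate_cdt <- function(params, init = cdt_initial_state(), horizon,
                         events = list(), report_times = NULL, step = 0.1,
                         rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (inherits(events, "cdt_event")) events <- list(events)
  if (length(events)) {
    stopifnot(all(vapply(events, inherits, TRUE, "cdt_event")))
    events <- events[order(vapply(events, `[[`, 0, "time"))]
    events <- Filter(function(e) e$time <= horizon, events)
  }
  init <- as_cdt_state(init)
  validate_params(params)

  times <- c(0, horizon, report_times)
  if (!is.na(step)) times <- c(times, seq(0, horizon, by = step))
  if (length(events)) times <- c(times, vapply(events, `[[`, 0, "time"))
  times <- sort(unique(times[times >= 0 & times <= horizon]))

  cuts <- vapply(events, `[[`, 0, "time")
  bounds <- unique(c(0, cuts, horizon))
  p_cur <- params
  state <- unclass(init)
  out_all <- NULL
  schedule <- data.frame(from = 0, t(as.numeric(p_cur)))
  names(schedule) <- c("from", CDT_PARAM_NAMES)

  for (i in seq_len(length(bounds) - 1)) {
    seg <- times[times >= bounds[i] & times <= bounds[i + 1]]
    if (length(seg) < 2) seg <- c(bounds[i], bounds[i + 1])
    sol <- integrate_segment(state, seg, p_cur, rtol, atol, compiled)
    if (nrow(sol) < length(seg) ||
        abs(sol[nrow(sol), 1] - seg[length(seg)]) > 1e-9)
      stop(sprintf("integration failed (step-size collapse) at t = %.6g min",
                   sol[nrow(sol), 1]))
    out_all <- rbind(out_all, if (is.null(out_all)) sol else sol[-1, , drop = FALSE])
    state <- sol[nrow(sol), -1]
    ev_here <- Filter(function(e) e$time == bounds[i + 1], events)
    for (e in ev_here) {
      p_cur <- apply_event(p_cur, e)
      schedule <- rbind(schedule,
                        setNames(data.frame(bounds[i + 1], t(as.numeric(p_cur))),
                                 names(schedule)))
    }
  }

  tr <- as.data.frame(out_all)
  names(tr) <- c("Time", CDT_SPECIES)
  tyr <- tr$TubTyr + tr$MTTyr
  detyr <- tr$TubDetyr + tr$MTDetyr
  tr$Tyr <- tyr
  tr$Detyr <- detyr
  tr$TyrDetyr <- ifelse(detyr < 1e-12, Inf, tyr / detyr)
  structure(tr, class = c("cdt_trace", "data.frame"),
            params = params, events = events, schedule = schedule,
            rtol = rtol, atol = atol)
}

integrate_segment <- function(state, times, params, rtol, atol, compiled) {
  y <- setNames(as.numeric(state[CDT_SPECIES]), CDT_SPECIES)
  if (compiled) {
    suppressWarnings(
      deSolve::lsoda(y, times, func = "cdt_derivs",
                     parms = as.numeric(params[CDT_PARAM_NAMES]),
                     dllname = "tyrcycle", initfunc = "cdt_initmod",
                     rtol = rtol, atol = atol))
  } else {
    suppressWarnings(
      deSolve::lsoda(y, times,
                     func = function(t, y, p) list(cdt_rhs(y, p)),
                     parms = params, rtol = rtol, atol = atol))
  }
}

#' Parameter values in force at a given time of a trace
#'
#' Resolves the piecewise-constant parameter schedule induced by events.
#'
#' @param trace a `"cdt_trace"`.
#' @param t time in minutes.
#' @return A `"cdt_params"` vector.
#' @export
params_at_time <- function(trace, t) {
  sch <- attr(trace, "schedule")
  row <- max(which(sch$from <= t))
  p <- as.numeric(sch[row, CDT_PARAM_NAMES])
  names(p) <- CDT_PARAM_NAMES
  structure(p, class = "cdt_params", variant = classify_variant(p))
}

#' @export
print.cdt_trace <- function(x, ...) {
  cat("Cycle simulation trace: ", nrow(x), " samples over [0, ",
      max(x$Time), "] min, ", length(attr(x, "events")), " event(s)\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Steady-state detection on a trace
#'
#' Declares the trace steady if, over the final `window` minutes, every
#' species' relative change (range over the window divided by the absolute
#' final value) is below `rel_tol`; species whose final value is below
#' `1e-9` uM are compared absolutely against `rel_tol` instead.
#'
#' @param trace a `"cdt_trace"`.
#' @param window length of the terminal window in minutes (must be shorter
#'   than the trace).
#' @param rel_tol convergence tolerance.
#' @return A list of class `"cdt_steady"` with elements `converged`, `state`
#'   (final [cdt_initial_state()]-like vector), `time`, and
#'   `max_rel_change`.  Non-convergence is a value, not an error.
#' @examples
#' tr <- simulate_cdt(cdt_params("proliferative"), horizon = 200, step = 1)
#' steady_state(tr)$converged
#' @export
steady_state <- function(trace, window = 10, rel_tol = 1e-6) {
  t_end <- max(trace$Time)
  if (window >= t_end) stop("window must be shorter than the trace duration")
  win <- trace[trace$Time >= t_end - window, CDT_SPECIES, drop = FALSE]
  final <- as.numeric(trace[nrow(trace), CDT_SPECIES])
  names(final) <- CDT_SPECIES
  span <- vapply(win, function(col) diff(range(col)), numeric(1))
  denom <- pmax(abs(final), 1e-9)
  rel <- ifelse(abs(final) < 1e-9, span, span / denom)
  structure(list(converged = all(rel < rel_tol),
                 state = structure(final, class = "cdt_state"),
                 time = t_end, max_rel_change = max(rel)),
            class = "cdt_steady")
}

#' @export
print.cdt_steady <- function(x, ...) {
  cat(if (x$converged) "converged" else "not converged",
      "at t =", x$time, "min (max relative change",
      format(x$max_rel_change, digits = 3), ")\n")
  print(setNames(as.numeric(x$state), CDT_SPECIES))
  invisible(x)
}

# Sparse-grid steady-state run: coarse transient samples plus a dense terminal
# window for the convergence check.  Shared by the robustness, uniqueness and
# synthetic-screen layers where thousands of such runs are needed.
simulate_to_steady <- function(params, init = cdt_initial_state(),
                               horizon = 10000, window = 10, rel_tol = 1e-6,
                               events = list(), ...) {
  times <- unique(sort(c(seq(0, min(100, horizon), length.out = 51),
                         seq(0, horizon, length.out = 101),
                         seq(horizon - window, horizon, length.out = 11))))
  tr <- simulate_cdt(params, init, horizon, events = events,
                     report_times = times, step = NA, ...)
  list(trace = tr, steady = steady_state(tr, window = window, rel_tol = rel_tol))
}

#' Dose-response scan of one kinetic parameter
#'
#' Mimics an in-silico dose-response experiment: the scanned parameter takes
#' each value on a linear grid (both endpoints included), the model is
#' simulated to `horizon`, and the observables at `horizon` are recorded.  For
#' a TCP inhibitor the scanned parameter is the detyrosination rate constant
#' `k1`; on the proliferative model the tyrosination status `TyrDetyr`
#' increases monotonically as `k1` decreases.
#'
#' @param params a [cdt_params()] vector.
#' @param init initial state.
#' @param scanned_param name of the kinetic parameter to scan.
#' @param lo,hi dose range (`lo <= hi`).
#' @param n_points number of doses (>= 1; a degenerate range yields one row).
#' @param horizon evaluation time in minutes (default 100).
#' @return A data frame of class `"cdt_dose_response"` with columns `dose`,
#'   `Tyr`, `Detyr`, `TyrDetyr`, `failed`.
#' @examples
#' dr <- dose_response(cdt_params("proliferative"), scanned_param = "k1",
#'                     lo = 0, hi = 10, n_points = 11)
#' @export
dose_response <- function(params, init = cdt_initial_state(), scanned_param,
                          lo, hi, n_points = 50, horizon = 100) {
  if (!scanned_param %in% CDT_PARAM_NAMES)
    stop("unknown kinetic parameter: ", scanned_param)
  if (lo > hi) stop("lo must be <= hi")
  if (n_points < 1) stop("n_points must be >= 1")
  doses <- if (lo == hi) lo else seq(lo, hi, length.out = n_points)
  rows <- lapply(doses, function(d) {
    p <- unclass(params)
    p[scanned_param] <- d
    p <- structure(p, class = "cdt_params", variant = "custom")
    tryCatch({
      tr <- simulate_cdt(p, init, horizon, report_times = horizon, step = NA)
      ob <- observables(as_cdt_state(tr[nrow(tr), CDT_SPECIES]))
      data.frame(dose = d, Tyr = ob[["Tyr"]], Detyr = ob[["Detyr"]],
                 TyrDetyr = ob[["TyrDetyr"]], failed = FALSE)
    }, error = function(e)
      data.frame(dose = d, Tyr = NA_real_, Detyr = NA_real_,
                 TyrDetyr = NA_real_, failed = TRUE))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cdt_dose_response", "data.frame"),
            scanned_param = scanned_param, horizon = horizon)
}

#' Export a trace as CSV
#'
#' Column order: `Time`, the six species, then `Tyr`, `Detyr`, `TyrDetyr`.
#'
#' @param trace a `"cdt_trace"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  cols <- c("Time", CDT_SPECIES, "Tyr", "Detyr", "TyrDetyr")
  write.csv(as.data.frame(trace)[, cols], path, row.names = FALSE)
  invisible(path)
}

total_tubulin <- function(trace) {
  rowSums(as.data.frame(trace)[, CDT_TUBULIN])
}
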