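# Monte-Carlo robustness of the equilibrium tyrosination status.
#
# One kinetic parameter is perturbed multiplicatively with log-normal noise
# whose coefficient of variation is prescribed; each perturbed model is
# simulated to steady state and scored against the equilibrium specification
# F(G(TyrDetyr = x)).  Log-normal sampling keeps rate constants positive at
# arbitrary cv; for a log-normal, cv^2 = exp(sigma^2) - 1, so
# sigma = sqrt(log(1 + cv^2)).

#' Robustness of the equilibrium tyrosination status to one parameter
#'
#' Draws `n_samples` perturbed values of `varied_param` (nominal value times a
#' log-normal factor with unit median and coefficient of variation `cv`),
#' simulates each model to steady state, and reports the mean satisfaction
#' degree of `F(G(TyrDetyr = x))` against the `objective` equilibrium value
#' together with the mean relative deviation `|TyrDetyr_ss - x| / x`.
#' Samples that fail to stabilize within `horizon` are excluded and counted.
#'
#' @param params a [cdt_params()] vector.
#' @param varied_param name of the perturbed rate constant.
#' @param cv coefficient of variation of the perturbed value (fraction;
#'   5.0 means 500%).
#' @param objective target equilibrium `TyrDetyr`; `NULL` uses the model's
#'   own unperturbed equilibrium value.
#' @param n_samples Monte-Carlo sample size.
#' @param seed integer seed.
#' @param init initial state.
#' @param horizon steady-state simulation horizon in minutes.
#' @return A list with `mean_satisfaction`, `mean_deviation`, `se_deviation`
#'   (standard error of the mean deviation), `n_effective`, `n_failed`, and
#'   `objective`.
#' @examples
#' \donttest{
#' robustness(cdt_params("proliferative"), "Vm2", cv = 1,
#'            objective = 10, n_samples = 50, seed = 1)
#' }
#' @export
robustness <- function(params, varied_param, cv, objective = NULL,
                       n_samples = 500, seed = 1,
                       init = cdt_initial_state(), horizon = 10000) {
  if (!varied_param %in% CDT_PARAM_NAMES)
    stop("unknown kinetic parameter: ", varied_param)
  if (cv < 0) stop("cv must be >= 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (is.null(objective)) {
    ss <- simulate_to_steady(params, init, horizon = horizon)
    objective <- unname(observables(ss$steady$state)["TyrDetyr"])
  }
  formula <- parse_formula("F(G(TyrDetyr = x))")
  nominal <- as.numeric(params[varied_param])

  factors <- if (cv == 0) rep(1, n_samples) else
    with_local_seed(seed, exp(rnorm(n_samples, 0, sqrt(log1p(cv^2)))))

  degrees <- deviations <- rep(NA_real_, n_samples)
  for (i in seq_len(n_samples)) {
    p <- unclass(params)
    p[varied_param] <- nominal * factors[i]
    p <- structure(p, class = "cdt_params", variant = "custom")
    res <- tryCatch(simulate_to_steady(p, init, horizon = horizon),
                    error = function(e) NULL)
    if (is.null(res) || !res$steady$converged) next
    sat <- satisfaction_degree(formula, res$trace, c(x = objective))
    degrees[i] <- sat$satisfaction_degree
    ratio <- unname(observables(res$steady$state)["TyrDetyr"])
    deviations[i] <- abs(ratio - objective) / objective
  }
  ok <- is.finite(degrees) & is.finite(deviations)
  list(mean_satisfaction = mean(degrees[ok]),
       mean_deviation = mean(deviations[ok]),
       se_deviation = if (sum(ok) > 1) sd(deviations[ok]) / sqrt(sum(ok)) else 0,
       n_effective = sum(ok), n_failed = n_samples - sum(ok),
       objective = objective)
}

#' Sensitivity curve over a grid of coefficients of variation
#'
#' Evaluates [robustness()] on an ascending `cv_grid` (starting at 0) with a
#' common seed stream, tracing how far the equilibrium tyrosination status
#' deviates as the perturbation of one parameter grows.
#'
#' @inheritParams robustness
#' @param cv_grid ascending coefficients of variation, first element 0.
#' @return A data frame of class `"cdt_sensitivity"` with columns `cv`,
#'   `mean_satisfaction`, `mean_deviation`, `n_effective`, `n_failed`.
#' @export
sensitivity_curve <- function(params, varied_param, cv_grid, objective = NULL,
                              n_samples = 500, seed = 1,
                              init = cdt_initial_state(), horizon = 10000) {
  if (is.unsorted(cv_grid) || cv_grid[1] != 0)
    stop("cv_grid must be ascending and start at 0")
  if (is.null(objective)) {
    ss <- simulate_to_steady(params, init, horizon = horizon)
    objective <- unname(observables(ss$steady$state)["TyrDetyr"])
  }
  rows <- lapply(seq_along(cv_grid), function(i) {
    r <- robustness(params, varied_param, cv_grid[i], objective = objective,
                    n_samples = n_samples, seed = seed + i - 1L,
                    init = init, horizon = horizon)
    data.frame(cv = cv_grid[i], mean_satisfaction = r$mean_satisfaction,
               mean_deviation = r$mean_deviation,
               se_deviation = r$se_deviation,
               n_effective = r$n_effective, n_failed = r$n_failed)
  })
  structure(do.call(rbind, rows),
            class = c("cdt_sensitivity", "data.frame"),
            param = varied_param, objective = objective,
            n_samples = n_samples, seed = seed)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
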