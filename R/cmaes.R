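#' Covariance Matrix Adaptation Evolution Strategy (box-constrained, minimizer)
#'
#' A standard (mu/mu_w, lambda)-CMA-ES for black-box continuous minimization
#' over a box.  The search runs in coordinates normalized to the unit box;
#' candidates are clipped to the box for evaluation, with a quadratic penalty
#' on the clipped distance so the sampling distribution is pulled back inside.
#' Defaults follow the usual recommendations: population
#' `4 + floor(3 log n)`, start at the box centre, initial step size one
#' quarter of the box width.
#'
#' @param fn objective to minimize; called with a numeric vector in
#'   `[lower, upper]`.
#' @param lower,upper finite box bounds (equal length).
#' @param x0 optional start point (defaults to the box centre).
#' @param sigma0 initial step size as a fraction of the box width.
#' @param max_evals evaluation budget.
#' @param stop_fitness stop as soon as a candidate reaches this value.
#' @param tol_fun stop when the population fitness spread falls below this.
#' @param tol_x stop when the search distribution collapses.
#' @param seed integer seed; identical seeds give identical runs.
#' @return List with `par` (best point found), `value`, `evals`, and
#'   `stopped_on`.
#' @examples
#' cma_es(function(x) sum((x - 0.3)^2), c(0, 0), c(1, 1), seed = 1)$par
#' @export
cma_es <- function(fn, lower, upper, x0 = NULL, sigma0 = 0.25,
                   max_evals = 2000, stop_fitness = -Inf,
                   tol_fun = 1e-10, tol_x = 1e-12, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(c(lower, upper))),
            all(lower < upper))
  n <- length(lower)
  width <- upper - lower
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  # normalized coordinates: z in [0,1]^n
  to_x <- function(z) lower + pmin(pmax(z, 0), 1) * width
  eval_z <- function(z) {
    overshoot <- sum(pmax(z - 1, 0)^2 + pmax(-z, 0)^2)
    fn(to_x(z)) + overshoot
  }

  xmean <- if (is.null(x0)) rep(0.5, n) else (x0 - lower) / width
  sigma <- sigma0
  lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  weights <- log(mu + 0.5) - log(seq_len(mu))
  weights <- weights / sum(weights)
  mueff <- 1 / sum(weights^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  pc <- ps <- numeric(n)
  B <- diag(n)
  D <- rep(1, n)
  C <- diag(n)
  invsqrtC <- diag(n)

  best_z <- xmean
  best_f <- Inf
  evals <- 0L
  stopped_on <- "max_evals"

  while (evals < max_evals) {
    arz <- matrix(rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    fit <- apply(arx, 2, eval_z)
    evals <- evals + lambda
    ord <- order(fit)
    if (fit[ord[1]] < best_f) {
      best_f <- fit[ord[1]]
      best_z <- arx[, ord[1]]
    }
    if (best_f <= stop_fitness) { stopped_on <- "stop_fitness"; break }

    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- drop(arx[, sel, drop = FALSE] %*% weights)
    zmean <- drop(arz[, sel, drop = FALSE] %*% weights)

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(B %*% zmean)
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * evals / lambda)) / n <
      2 + 4 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * (xmean - xold) / sigma

    artmp <- (arx[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (weights * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D2 <- pmax(eig$values, .Machine$double.eps)
    D <- sqrt(D2)
    B <- eig$vectors
    invsqrtC <- B %*% diag(1 / D, n) %*% t(B)

    if (diff(range(fit)) < tol_fun && sigma < 0.05) {
      stopped_on <- "tol_fun"; break
    }
    if (sigma * max(D) < tol_x) { stopped_on <- "tol_x"; break }
    if (max(D) / min(D) > 1e7) { stopped_on <- "condition"; break }
  }

  list(par = to_x(best_z), value = best_f, evals = evals,
       stopped_on = stopped_on)
}
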