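pN <- cdt_params("neuronal")
pP <- cdt_params("proliferative")
TENFOLD <- paste0("F(Time == 5 /\\ Tyr = factor1 * Detyr",
                  " /\\ F(Time == 20 /\\ Tyr = factor2 * Detyr))")
OBJ10 <- c(factor1 = 10, factor2 = 10)

test_that("the CMA-ES core finds quadratic optima inside the box", {
  sphere <- function(x) sum((x - c(0.3, 0.7))^2)
  r <- cma_es(sphere, c(0, 0), c(1, 1), max_evals = 600, seed = 1)
  expect_equal(r$par, c(0.3, 0.7), tolerance = 1e-3)
  # boundary optimum: minimizer outside the box projects onto its edge
  edge <- cma_es(function(x) sum((x - c(2, 0.5))^2), c(0, 0), c(1, 1),
                 max_evals = 600, seed = 1)
  expect_equal(edge$par[1], 1, tolerance = 1e-3)
  expect_true(all(edge$par >= 0 & edge$par <= 1))
})

test_that("searches are reproducible bit-wise under a fixed seed", {
  r1 <- cma_es(function(x) sum(x^2), c(-1, -1), c(1, 1), max_evals = 200, seed = 7)
  r2 <- cma_es(function(x) sum(x^2), c(-1, -1), c(1, 1), max_evals = 200, seed = 7)
  expect_identical(r1, r2)
  s1 <- search_parameters("F(Time == 5 /\\ Tyr = f1)", c(f1 = 2.3),
                          bounds = list(mc1 = c(0, 10)), base_params = pN,
                          evals = 120, restarts = 2, seed = 5)
  s2 <- search_parameters("F(Time == 5 /\\ Tyr = f1)", c(f1 = 2.3),
                          bounds = list(mc1 = c(0, 10)), base_params = pN,
                          evals = 120, restarts = 2, seed = 5)
  expect_identical(s1$par, s2$par)
  expect_identical(s1$per_restart, s2$per_restart)
})

test_that("the Michaelis-constant fit recovers the 2.5 uM transient objective", {
  fit <- search_parameters("F(Time == 5 /\\ Tyr = factor1)", c(factor1 = 2.5),
                           bounds = list(mc1 = c(0, 10), mc2 = c(0, 10)),
                           base_params = pN, evals = 500, restarts = 1, seed = 1)
  expect_gte(fit$degree, 0.99)
  expect_true(all(fit$par >= 0 & fit$par <= 10))
})

test_that("a specification already satisfied by the baseline returns it unchanged", {
  # kp1 is constant on every trace, so the objective is achievable everywhere
  res <- search_parameters("F(Time == 5 /\\ kp1 = v)", c(v = 0.975),
                           bounds = list(mc1 = c(0, 10)), base_params = pN,
                           evals = 200, restarts = 1, seed = 1)
  expect_equal(res$degree, 1)
  expect_equal(unname(res$par["mc1"]), 2.75)
  expect_equal(res$evals, 1L)
})

test_that("searchable-set validation rejects fixed and duplicate parameters", {
  expect_error(search_parameters(TENFOLD, OBJ10,
                                 bounds = list(kp1 = c(0, 100)),
                                 base_params = pN),
               "not searchable")
  expect_error(search_parameters(TENFOLD, OBJ10,
                                 bounds = list(km1 = c(0, 100), km1 = c(0, 100)),
                                 base_params = pN),
               "duplicate")
  expect_error(search_parameters(TENFOLD, OBJ10,
                                 bounds = list(km1 = c(100, 0)),
                                 base_params = pN),
               "lower < upper")
})

test_that("the tyrosination/depolymerization pair satisfies the tenfold specification", {
  res <- search_parameters(TENFOLD, OBJ10,
                           bounds = list(Vm2 = c(0, 100), km1 = c(0, 100)),
                           base_params = pN, evals = 2000, restarts = 3, seed = 1)
  expect_gte(res$degree, 0.99)
})

test_that("searching a pair does at least as well as either member alone", {
  members <- c("km1", "Vm2")
  singles <- vapply(members, function(pn)
    search_parameters(TENFOLD, OBJ10, bounds = setNames(list(c(0, 100)), pn),
                      base_params = pN, evals = 600, restarts = 1,
                      seed = 3)$degree, numeric(1))
  pair <- search_parameters(TENFOLD, OBJ10,
                            bounds = list(km1 = c(0, 100), Vm2 = c(0, 100)),
                            base_params = pN, evals = 600, restarts = 1,
                            seed = 3)$degree
  expect_gte(pair, max(singles) - 0.02)
})

test_that("sweeps validate their inputs", {
  expect_error(pair_sweep(TENFOLD, OBJ10, parameters = c("km1", "km1")),
               "duplicate")
  expect_error(pair_sweep(TENFOLD, OBJ10, parameters = "km1"), "at least two")
  expect_error(single_param_sweep(TENFOLD, OBJ10, parameters = c("kp1", "km1")),
               "not searchable")
})

test_that("a trivially satisfiable sweep reports degree 1 everywhere", {
  sw <- single_param_sweep("F(Time == 5 /\\ kp1 = v)", c(v = 0.975),
                           base_params = pN, parameters = c("km1", "mc2"),
                           evals = 100, restarts = 1, seed = 1)
  expect_equal(sw$best_degree, c(1, 1))
})

test_that("the minimal-change fit returns the satisfying point nearest the baseline", {
  mc <- minimal_change_search(base_params = pN, evals = 800, restarts = 2,
                              seed = 2)
  expect_gte(mc$behaviour_degree, 0.99)
  # the behavioural constraints hold: tenfold ratio at both anchors
  expect_equal(unname(mc$ratios), c(10, 10), tolerance = 0.05)
  # both parameters increase strongly from the neuronal values
  expect_gt(mc$fold_change[["km1"]], 10)
  expect_gt(mc$fold_change[["Vm2"]], 10)
  expect_true(all(mc$par >= c(0, 0) & mc$par <= c(15, 30)))
})

test_that("an already-satisfying baseline is a fixed point of the minimal-change fit", {
  mc <- minimal_change_search(base_params = pP, evals = 600, restarts = 1,
                              seed = 4)
  expect_equal(unname(mc$par["Vm2"]), 7.70, tolerance = 0.15)
  expect_equal(unname(mc$par["km1"]), 11.74, tolerance = 0.15)
  expect_equal(unname(mc$fold_change), c(1, 1), tolerance = 0.02)
})

test_that("landscape scans honour the grid contract", {
  ls <- scan_landscape(TENFOLD, OBJ10,
                       axes = list(Vm2 = c(0, 15), km1 = c(0, 30)),
                       resolution = 8, base_params = pN)
  expect_equal(dim(ls$degree), c(8, 8))
  expect_equal(range(ls$grid1), c(0, 15))
  expect_equal(range(ls$grid2), c(0, 30))
  expect_true(all(ls$degree > 0 & ls$degree <= 1, na.rm = TRUE))
  # trivially satisfiable formula: every cell scores 1
  lt <- scan_landscape("F(Time == 5 /\\ kp1 = v)", c(v = 0.975),
                       axes = list(Vm2 = c(0, 5), km1 = c(0, 5)),
                       resolution = 3, base_params = pN)
  expect_true(all(lt$degree == 1))
  expect_error(scan_landscape(TENFOLD, OBJ10,
                              axes = list(Vm2 = c(0, 1)), resolution = 5),
               "exactly two")
})

test_that("the grid cell at the proliferative parameter point satisfies fully", {
  fn <- tyrcycle:::degree_evaluator(parse_formula(TENFOLD), OBJ10,
                                    c("Vm2", "km1"), pN, cdt_initial_state())
  expect_gte(fn(c(7.70, 11.74)), 0.99)
})
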