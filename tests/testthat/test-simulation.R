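pN <- cdt_params("neuronal")
pP <- cdt_params("proliferative")

test_that("traces start at 0, contain requested report times, and conserve tubulin", {
  tr <- simulate_cdt(pN, horizon = 30, report_times = c(1.234, 17.5), step = 0.5)
  expect_equal(tr$Time[1], 0)
  expect_true(all(c(1.234, 17.5, 30) %in% tr$Time))
  expect_false(is.unsorted(tr$Time, strictly = TRUE))
  tot <- tyrcycle:::total_tubulin(tr)
  expect_lt(max(abs(tot - tot[1]) / tot[1]), 1e-6)
})

test_that("a vanishing horizon reproduces the initial state", {
  tr <- simulate_cdt(pN, horizon = 1e-8, step = NA)
  expect_equal(as.numeric(tr[nrow(tr), tyrcycle:::CDT_SPECIES]),
               as.numeric(cdt_initial_state()), tolerance = 1e-7)
})

test_that("the neuronal model ends detyrosination-dominated, the proliferative stays tyrosinated", {
  tr <- simulate_cdt(pN, horizon = 300, step = 1)
  fin <- tr[nrow(tr), ]
  expect_equal(which.max(as.numeric(fin[tyrcycle:::CDT_TUBULIN])), 3) # MTDetyr
  expect_lt(fin$Tyr, 0.5)          # tyrosinated pools nearly drained
  expect_gt(fin$Detyr / fin$Tyr, 10)
  trP <- simulate_cdt(pP, horizon = 20, report_times = c(5, 20), step = NA)
  expect_equal(trP$TyrDetyr[trP$Time == 5], 10, tolerance = 0.05)
  expect_equal(trP$TyrDetyr[trP$Time == 20], 10, tolerance = 0.05)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  tt <- c(0, 1, 5, 20, 60)
  a <- simulate_cdt(pN, horizon = 60, report_times = tt, step = NA)
  b <- simulate_cdt(pN, horizon = 60, report_times = tt, step = NA,
                    compiled = FALSE)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-8)
})

test_that("steady-state detection accepts constant and converged traces", {
  const <- make_synthetic_trace(seq(0, 100, 5),
                                list(TubTyr = 2, TubDetyr = 1, MTDetyr = 1,
                                     MTTyr = 1, TTL = 1, TCP = 1))
  st <- steady_state(const)
  expect_true(st$converged)
  expect_equal(as.numeric(st$state["TubTyr"]), 2)

  res <- tyrcycle:::simulate_to_steady(pN, horizon = 10000)
  expect_true(res$steady$converged)
  # frozen value of the model's own equilibrium tyrosination status
  expect_equal(unname(observables(res$steady$state)["TyrDetyr"]),
               0.0633266, tolerance = 1e-4)
})

test_that("a slowly decaying trace is reported as not converged", {
  # half-life 100 min, horizon 120 min << 5 half-lives: relative change over
  # the last 10 min is 1 - 2^(-10/100) = 6.7%, far above tolerance
  decay <- make_synthetic_trace(seq(0, 120, 1),
                                list(TubTyr = function(t) 5 * 2^(-t / 100),
                                     TTL = 1, TCP = 1))
  st <- steady_state(decay)
  expect_false(st$converged)
  expect_gt(st$max_rel_change, 0.05)
  expect_error(steady_state(decay, window = 200), "shorter than")
})

test_that("events fire once at their trigger time with the preset fold values", {
  evs <- perturbation_preset(pN, c("km1", "Vm2"), 10, 60)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$assignments, c(km1 = 4.78, Vm2 = 2.0))
  expect_equal(evs[[1]]$time, 60)
  tr <- simulate_cdt(pN, horizon = 80, events = evs, step = 0.5)
  expect_equal(as.numeric(params_at_time(tr, 59)[c("km1", "Vm2")]),
               c(0.478, 0.2))
  expect_equal(as.numeric(params_at_time(tr, 60)[c("km1", "Vm2")]),
               c(4.78, 2.0))
  tot <- tyrcycle:::total_tubulin(tr)
  expect_lt(max(abs(tot - tot[1]) / tot[1]), 1e-6)   # conserved across firing
})

test_that("null and out-of-horizon events leave the trajectory unchanged", {
  base <- simulate_cdt(pN, horizon = 40, step = 0.5)
  noop <- simulate_cdt(pN, horizon = 40, step = 0.5,
                       events = perturbation_preset(pN, "Vm2", 1, 20))
  # the integration restarts at the (ineffective) event, so agreement is to
  # integrator accuracy rather than bit-identical
  expect_equal(noop$TyrDetyr, base$TyrDetyr, tolerance = 1e-6)
  late <- simulate_cdt(pN, horizon = 40, step = 0.5,
                       events = list(cdt_event(90, Vm2 = 2)))
  expect_identical(late$MTDetyr, base$MTDetyr)   # bit-identical shared grid
})

test_that("stacked fold events compound on the value in force", {
  evs <- list(cdt_event(10, Vm2 = 2, mode = "fold"),
              cdt_event(20, Vm2 = 3, mode = "fold"))
  tr <- simulate_cdt(pN, horizon = 30, events = evs, step = 1)
  expect_equal(as.numeric(params_at_time(tr, 15)["Vm2"]), 0.4)
  expect_equal(as.numeric(params_at_time(tr, 25)["Vm2"]), 1.2)
})

test_that("event construction is validated", {
  expect_error(cdt_event(-5, Vm2 = 1), "> 0")
  expect_error(cdt_event(5, 3), "named")
  expect_error(cdt_event(5, Vm2 = 1, Vm2 = 2), "at most once")
  expect_error(cdt_event(5, nope = 1), "unknown kinetic parameter")
  expect_error(perturbation_preset(pN, "nope", 10, 60), "unknown")
})

test_that("halving the integrator tolerances leaves the equilibrium unchanged", {
  r1 <- tyrcycle:::simulate_to_steady(pN, horizon = 10000)
  r2 <- tyrcycle:::simulate_to_steady(pN, horizon = 10000,
                                      rtol = 5e-9, atol = 5e-11)
  v1 <- observables(r1$steady$state)["TyrDetyr"]
  v2 <- observables(r2$steady$state)["TyrDetyr"]
  expect_lt(abs(v1 - v2) / v1, 1e-6)
})

test_that("dose-response scans record the observables per dose", {
  dr <- dose_response(pP, scanned_param = "k1", lo = 0, hi = 10,
                      n_points = 21, horizon = 100)
  expect_equal(nrow(dr), 21)
  expect_equal(dr$dose, seq(0, 10, length.out = 21))
  # no detyrosination flux at dose 0: ratio is +Inf
  expect_equal(dr$TyrDetyr[1], Inf)
  expect_equal(dr$Detyr[1], 0)
  # a TCP inhibitor raises the tyrosination status monotonically
  on_doses <- dr$TyrDetyr[dr$dose > 0]
  expect_true(all(diff(on_doses) < 0))
  single <- dose_response(pP, scanned_param = "k1", lo = 2, hi = 2)
  expect_equal(nrow(single), 1)
  expect_error(dose_response(pP, scanned_param = "k1", lo = 5, hi = 1), "<=")
})

test_that("trace CSV export round-trips", {
  tr <- simulate_cdt(pN, horizon = 5, step = 1)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read.csv(f)
  expect_equal(names(back)[1:2], c("Time", "TubTyr"))
  expect_equal(back$MTDetyr, tr$MTDetyr, tolerance = 1e-12)
  unlink(f)
})
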