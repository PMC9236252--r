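pP <- cdt_params("proliferative")

test_that("the inhibitor transfer is sigmoidal between 1 and 0", {
  expect_equal(hill_multiplier(0), 1)
  expect_equal(hill_multiplier(5, ec50 = 5), 0.5)
  d <- seq(0, 50, 2)
  m <- hill_multiplier(d)
  expect_true(all(diff(m) < 0))
  expect_true(all(m > 0 & m <= 1))
  expect_error(hill_multiplier(-1), ">= 0")
})

test_that("noiseless wells are deterministic copies of the model prediction", {
  d <- assay_design(n_negative = 1, n_positive = 0, cells_per_well = 5,
                    cv = 0, gain = 1000)
  cells <- generate_cells(d, pP, seed = 1)
  expect_equal(nrow(cells), 5)
  expect_length(unique(cells$tyr_intensity), 1)
  ss <- tyrcycle:::simulate_to_steady(pP)$steady$state
  ob <- observables(ss)
  expect_equal(cells$tyr_intensity[1], 1000 * ob[["Tyr"]], tolerance = 1e-8)
  expect_equal(cells$detyr_intensity[1], 1000 * ob[["Detyr"]], tolerance = 1e-8)
})

test_that("well means recover the tenfold ratio under realistic noise", {
  d <- assay_design(n_negative = 2, n_positive = 0, cells_per_well = 500,
                    cv = 0.3)
  cells <- generate_cells(d, pP, seed = 42)
  q <- quantify_wells(cells)
  # ratio of well means, not mean of per-cell ratios (the latter is biased
  # upwards for log-normal noise)
  expect_equal(q$ratio, rep(10, 2), tolerance = 0.05)
  expect_true(all(cells$tyr_intensity > 0 & cells$detyr_intensity > 0))
})

test_that("tables are reproducible per seed and vary across seeds", {
  d <- assay_design(n_negative = 1, n_positive = 1, cells_per_well = 20)
  a <- generate_cells(d, pP, seed = 9)
  b <- generate_cells(d, pP, seed = 9)
  c2 <- generate_cells(d, pP, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$tyr_intensity, c2$tyr_intensity))
})

test_that("increasing TCP-inhibitor dose raises the expected well ratio", {
  d <- assay_design(n_negative = 0, n_positive = 0,
                    doses = c(0.5, 2, 5, 10, 20), cells_per_well = 1, cv = 0)
  cells <- generate_cells(d, pP, seed = 1)
  q <- quantify_wells(cells)
  q <- q[order(q$dose), ]
  expect_true(all(diff(q$ratio) > 0))
})

test_that("well quantification matches hand-computed summaries", {
  tab <- structure(
    data.frame(well = c("W1", "W1", "W1", "W2"),
               condition = "negative", dose = NA_real_,
               tyr_intensity = c(10, 20, 30, 7),
               detyr_intensity = c(2, 4, 6, 14)),
    class = c("cdt_cell_table", "data.frame"))
  q <- quantify_wells(tab)
  w1 <- q[q$well == "W1", ]
  expect_equal(w1$tyr_mean, 20)
  expect_equal(w1$tyr_sd, 10)
  expect_equal(w1$detyr_mean, 4)
  expect_equal(w1$ratio, 5)
  w2 <- q[q$well == "W2", ]
  expect_equal(w2$tyr_sd, 0)     # single-cell well
  expect_equal(w2$ratio, 0.5)
  expect_error(quantify_wells(tab[0, ]), "empty")
})

test_that("the Z'-factor reproduces its defining arithmetic and bands", {
  # sd_p = 1, sd_n = 0.5, means 10 and 1: 1 - 3 * 1.5 / 9 = 0.5
  pos <- c(9, 10, 11)          # mean 10, sd 1
  neg <- c(0.5, 1, 1.5)        # mean 1, sd 0.5
  expect_equal(zprime(pos, neg), 0.5)
  expect_equal(zprime(c(10, 10, 10), c(1, 1, 1)), 1)  # upper bound
  expect_error(zprime(c(1, 2), c(1.5, 1.5)), "equal")
  expect_error(zprime(1, c(1, 2)), "at least two")
  # interpretation bands on constructed normal samples
  set.seed(1)
  tight <- zprime(rnorm(500, 10, 0.3), rnorm(500, 1, 0.3))
  overlapping <- zprime(rnorm(500, 2, 2), rnorm(500, 1, 2))
  expect_gte(tight, 0.5)
  expect_lt(overlapping, 0)
})

test_that("a synthetic proliferative plate separates its controls well", {
  d <- assay_design(n_negative = 6, n_positive = 6, cells_per_well = 300,
                    cv = 0.3)
  cells <- generate_cells(d, pP, seed = 11)
  q <- quantify_wells(cells)
  # positive controls (microtubule-stabilizer-like) shift towards
  # detyrosination, negatives sit at the tenfold tyrosinated ratio
  zp <- zprime(q$ratio[q$condition == "positive"],
               q$ratio[q$condition == "negative"])
  expect_gte(zp, 0.5)
})

test_that("cell tables round-trip through CSV with validation", {
  d <- assay_design(n_negative = 1, n_positive = 1, cells_per_well = 10)
  cells <- generate_cells(d, pP, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cell_table(cells, f)
  back <- read_cell_table(f)
  expect_equal(back$tyr_intensity, cells$tyr_intensity, tolerance = 1e-12)
  expect_s3_class(back, "cdt_cell_table")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_cell_table(bad), "columns")
  unlink(c(f, bad))
})

test_that("design validation rejects inconsistent settings", {
  expect_error(assay_design(cv = -1), ">= 0")
  expect_error(assay_design(n_negative = 0, n_positive = 0), "no wells")
  expect_error(assay_design(target_param = "zzz"), "unknown target")
})
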