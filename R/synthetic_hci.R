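# Synthetic high-content-imaging stand-in.
#
# Real screens image immunostained cells and quantify per-cell fluorescence
# of tyrosinated and detyrosinated tubulin.  This module emulates those
# single-cell tables from the model: each well's condition modulates kinetic
# parameters (a compound acting through a sigmoidal dose -> multiplier
# transfer), the modulated model is run to steady state, and per-cell channel
# intensities are drawn log-normally around means proportional to the
# steady-state Tyr and Detyr concentrations.  All noise parameters are
# synthetic declarations, not estimates of any real assay.

#' Sigmoidal dose-to-multiplier transfer of an inhibitor
#'
#' Hill-type inhibition transfer `1 - dose^h / (dose^h + ec50^h)`, mapping a
#' compound dose (uM) to the factor applied to its target rate constant: 1 at
#' dose 0, 1/2 at `ec50`, approaching 0 at saturating dose.  A TCP inhibitor
#' such as parthenolide is modelled by applying this multiplier to the
#' detyrosination rate constant `k1`.
#'
#' @param dose dose(s) in uM, >= 0.
#' @param ec50 half-maximal inhibitory dose (uM).
#' @param h Hill coefficient.
#' @return Multiplier(s) in (0, 1].
#' @examples
#' hill_multiplier(c(0, 5, 50))
#' @export
hill_multiplier <- function(dose, ec50 = 5, h = 2) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (ec50 <= 0 || h <= 0) stop("ec50 and h must be > 0")
  1 - dose^h / (dose^h + ec50^h)
}

#' Define a synthetic screening plate
#'
#' Builds the well-level design of a synthetic assay.  Each well has a
#' condition label, an optional dose, a cell count, and a ground-truth
#' parameter modulation: compound wells scale `target_param` by
#' `hill_multiplier(dose)`, positive-control wells apply
#' `positive_multipliers` (default: a microtubule stabilizer that slows both
#' depolymerization reactions tenfold, shifting the plate towards
#' detyrosination), and negative-control wells leave the model untouched.
#'
#' @param n_negative,n_positive numbers of control wells.
#' @param doses compound doses in uM (one well per dose; may be empty).
#' @param cells_per_well cells per well.
#' @param cv multiplicative cell-to-cell noise (coefficient of variation).
#' @param gain channel mean intensity per uM of species (AU/uM).
#' @param target_param parameter modulated by the compound.
#' @param ec50,h compound transfer parameters (see [hill_multiplier()]).
#' @param positive_multipliers named multipliers for positive-control wells.
#' @return A list of class `"cdt_assay_design"` with the per-well table and
#'   the noise/transfer settings.
#' @examples
#' assay_design(n_negative = 2, n_positive = 2, doses = c(1, 5, 10))
#' @export
assay_design <- function(n_negative = 8, n_positive = 8, doses = numeric(),
                         cells_per_well = 500, cv = 0.3, gain = 1000,
                         target_param = "k1", ec50 = 5, h = 2,
                         positive_multipliers = c(km1 = 0.1, km2 = 0.1)) {
  if (cv < 0) stop("cv must be >= 0")
  if (gain <= 0) stop("gain must be > 0")
  if (cells_per_well < 1) stop("cells_per_well must be >= 1")
  if (!target_param %in% CDT_PARAM_NAMES)
    stop("unknown target parameter: ", target_param)
  wells <- rbind(
    if (n_negative > 0)
      data.frame(condition = "negative", dose = NA_real_,
                 well = sprintf("N%02d", seq_len(n_negative))),
    if (n_positive > 0)
      data.frame(condition = "positive", dose = NA_real_,
                 well = sprintf("P%02d", seq_len(n_positive))),
    if (length(doses))
      data.frame(condition = "compound", dose = doses,
                 well = sprintf("C%02d", seq_along(doses))))
  if (is.null(wells)) stop("design has no wells")
  wells$n_cells <- cells_per_well
  structure(list(wells = wells[, c("well", "condition", "dose", "n_cells")],
                 cv = cv, gain = gain, target_param = target_param,
                 ec50 = ec50, h = h,
                 positive_multipliers = positive_multipliers),
            class = "cdt_assay_design")
}

#' @export
print.cdt_assay_design <- function(x, ...) {
  cat("Synthetic assay design:", nrow(x$wells), "wells, cv =", x$cv,
      ", gain =", x$gain, "AU/uM\n")
  print(table(x$wells$condition))
  invisible(x)
}

well_multipliers <- function(design, well_row) {
  switch(well_row$condition,
    negative = numeric(),
    positive = design$positive_multipliers,
    compound = setNames(hill_multiplier(well_row$dose, design$ec50, design$h),
                        design$target_param),
    stop("unknown condition: ", well_row$condition))
}

#' Generate a synthetic single-cell intensity table
#'
#' For each well of the design, applies the well's parameter modulation to
#' `params`, simulates to steady state, and draws per-cell channel
#' intensities: `tyr_intensity` and `detyr_intensity` are log-normal with
#' means `gain * Tyr` and `gain * Detyr` and coefficient of variation `cv`
#' (so well means converge to the model's predicted concentrations; at
#' `cv = 0` every cell is identical).  Deterministic given `seed`.
#'
#' @param design an [assay_design()].
#' @param params baseline [cdt_params()].
#' @param seed integer seed.
#' @param init initial state.
#' @param horizon steady-state horizon in minutes.
#' @return A data frame of class `"cdt_cell_table"`: one row per cell with
#'   `well`, `condition`, `dose`, `tyr_intensity`, `detyr_intensity`.
#' @examples
#' \donttest{
#' d <- assay_design(n_negative = 1, n_positive = 1, cells_per_well = 10)
#' cells <- generate_cells(d, cdt_params("proliferative"), seed = 1)
#' }
#' @export
generate_cells <- function(design, params, seed = 1,
                           init = cdt_initial_state(), horizon = 10000) {
  stopifnot(inherits(design, "cdt_assay_design"))
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(design$wells)), function(i) {
      w <- design$wells[i, ]
      mult <- well_multipliers(design, w)
      p <- unclass(params)
      p[names(mult)] <- p[names(mult)] * mult
      p <- structure(p, class = "cdt_params", variant = "custom")
      res <- tryCatch(simulate_to_steady(p, init, horizon = horizon),
                      error = function(e) NULL)
      if (is.null(res) || !res$steady$converged)
        stop("well ", w$well, " did not reach steady state")
      ob <- observables(res$steady$state)
      n <- w$n_cells
      draw <- function(mu) {
        if (design$cv == 0) return(rep(mu, n))
        sdlog <- sqrt(log1p(design$cv^2))
        # meanlog chosen so the arithmetic mean is gain * concentration
        exp(rnorm(n, log(mu) - sdlog^2 / 2, sdlog))
      }
      data.frame(well = w$well, condition = w$condition, dose = w$dose,
                 tyr_intensity = draw(design$gain * ob[["Tyr"]]),
                 detyr_intensity = draw(design$gain * ob[["Detyr"]]))
    })
    structure(do.call(rbind, rows),
              class = c("cdt_cell_table", "data.frame"),
              design = design, seed = seed)
  })
}

#' Per-well summary of a single-cell table
#'
#' Mean and standard deviation of each channel per well, plus the
#' ratio-of-means `mean(tyr) / mean(detyr)` — the well-level estimator of the
#' tyrosination status (per-cell ratios of log-normals are biased upwards, so
#' the ratio of well means is used, matching how population-averaged
#' intensity descriptors are computed).
#'
#' @param table a `"cdt_cell_table"`.
#' @return Data frame with one row per well: `well`, `condition`, `dose`,
#'   `n_cells`, `tyr_mean`, `tyr_sd`, `detyr_mean`, `detyr_sd`, `ratio`.
#' @export
quantify_wells <- function(table) {
  if (!nrow(table)) stop("empty cell table")
  split_wells <- split(table, table$well)
  rows <- lapply(split_wells, function(w) {
    data.frame(well = w$well[1], condition = w$condition[1], dose = w$dose[1],
               n_cells = nrow(w),
               tyr_mean = mean(w$tyr_intensity),
               tyr_sd = if (nrow(w) > 1) sd(w$tyr_intensity) else 0,
               detyr_mean = mean(w$detyr_intensity),
               detyr_sd = if (nrow(w) > 1) sd(w$detyr_intensity) else 0,
               ratio = mean(w$tyr_intensity) / mean(w$detyr_intensity))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$well), ]
}

#' Z'-factor of a screening readout
#'
#' Assay-quality statistic `1 - 3 (sd_p + sd_n) / |mean_p - mean_n|`
#' separating the positive- and negative-control distributions.  Values in
#' `[0.5, 1)` indicate well-separated controls (a large separation band),
#' `[0, 0.5)` a small separation band, and negative values overlapping
#' controls.
#'
#' @param pos_values,neg_values readout values (e.g. per-cell or per-well
#'   tyrosination ratios) for the positive and negative controls; each needs
#'   at least two values, with distinct group means.
#' @return The Z'-factor (a single number, at most 1).
#' @examples
#' zprime(rnorm(100, 10, 1), rnorm(100, 1, 0.5))
#' @export
zprime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop("each control group needs at least two values")
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n)
    stop("control means are equal; separation is undefined")
  1 - 3 * (sd(pos_values) + sd(neg_values)) / abs(mu_p - mu_n)
}

#' Write / read a single-cell table as CSV
#'
#' Header: `well, condition, dose, tyr_intensity, detyr_intensity`.
#'
#' @param table a `"cdt_cell_table"` (for writing).
#' @param path file path.
#' @return `write_cell_table`: `path` invisibly; `read_cell_table`: the table.
#' @export
write_cell_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "condition", "dose", "tyr_intensity", "detyr_intensity")
  if (!all(need %in% names(tab)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$tyr_intensity <= 0) || any(tab$detyr_intensity <= 0))
    stop("intensities must be strictly positive")
  structure(tab, class = c("cdt_cell_table", "data.frame"))
}
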