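#' Required nitrogen re-allocation between two optimal allocations
#'
#' The total fraction of photosynthetic nitrogen that must move between the
#' three nitrogen pools to convert one optimal allocation into another:
#' `delta_n = sum_i |n_i^evo - n_i^growth|` over `i` in (Etot, C4, Jmax).
#' The LET proportion `p` is an energy/hardware-wiring variable, not a
#' nitrogen pool, and is excluded. `delta_n` lies in `[0, 2]` and is symmetric
#' in its arguments.
#'
#' @param evo,growth [allocation()] objects (or `photo_optim` results, whose
#'   allocations are taken).
#' @return An object of class `photo_delta_n` with fields `delta_n`,
#'   `per_pool`, `labels`.
#' @examples
#' a <- allocation(0.5, 0.1, 0.4, p = 0.9)
#' b <- allocation(0.4, 0.2, 0.4, p = 0.8)
#' delta_n(a, b)$delta_n  # 0.2
#' @export
delta_n <- function(evo, growth) {
  if (inherits(evo, "photo_optim")) evo <- evo$alloc
  if (inherits(growth, "photo_optim")) growth <- growth$alloc
  stopifnot(inherits(evo, "photo_allocation"), inherits(growth, "photo_allocation"))
  per_pool <- c(Etot = abs(evo$n_Etot - growth$n_Etot),
                C4 = abs(evo$n_C4 - growth$n_C4),
                Jmax = abs(evo$n_Jmax - growth$n_Jmax))
  structure(list(delta_n = sum(per_pool), per_pool = per_pool,
                 labels = c(evo$scenario %||% "evo", growth$scenario %||% "growth")),
            class = "photo_delta_n")
}

#' @export
print.photo_delta_n <- function(x, ...) {
  cat("<photo_delta_n> ", paste(x$labels, collapse = " vs "), ": delta_n = ",
      signif(x$delta_n, 4), "\n  per pool: ",
      paste(names(x$per_pool), signif(x$per_pool, 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

.MEAS_QUANTITIES <- c("A", "Chl", "PSII", "cyt_f", "Rubisco_N", "C4_N",
                      "thylakoid_N")
.X_KINDS <- c("Ci", "T", "N", "none")

#' Validate a measurement table
#'
#' A measurement table is a tibble with columns `curve_id`, `x_kind` (one of
#' `"Ci"`, `"T"`, `"N"`, `"none"`), `x_value`, `quantity` (one of `A`, `Chl`,
#' `PSII`, `cyt_f`, `Rubisco_N`, `C4_N`, `thylakoid_N`), `value`, `se`, `n`.
#'
#' @param data a data frame.
#' @return The validated tibble (invisibly coerced with [tibble::as_tibble()]).
#' @export
measurement_table <- function(data) {
  need <- c("curve_id", "x_kind", "x_value", "quantity", "value", "se", "n")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(data$x_kind), .X_KINDS)
  if (length(bad_kind)) {
    stop("unknown x_kind value(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  bad_q <- setdiff(unique(data$quantity), .MEAS_QUANTITIES)
  if (length(bad_q)) {
    stop("unknown quantity name(s): ", paste(bad_q, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(data$se) & data$se < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(data[, need])
}

#' Model-predicted photosynthetic pool quantities
#'
#' Predicts the measurable resource-allocation quantities implied by an
#' allocation in an environment: net assimilation `A` (umol CO2 m-2 s-1),
#' chlorophyll `Chl` (umol m-2), photosystem II content `PSII` (umol m-2),
#' cytochrome f `cyt_f` (umol m-2, summed over both chains), and the nitrogen
#' amounts in each pool, `Rubisco_N`, `C4_N`, `thylakoid_N` (umol N m-2).
#'
#' @inheritParams simulate_assimilation
#' @param curve_id label stamped on the rows.
#' @return A measurement table (see [measurement_table()]) with `x_kind` "none".
#' @export
predict_pools <- function(species, env, alloc, partition,
                          constants = stoichiometry_constants(),
                          tparams = temperature_params(),
                          curve_id = "pools") {
  res <- simulate_assimilation(species, env, alloc, partition, constants,
                               tparams)
  caps <- res$capacities
  vals <- c(
    A = res$A,
    Chl = caps$Chl,
    PSII = caps$composition$PSII * caps$Chl / 1000,
    cyt_f = (caps$composition$cyt_LET + caps$composition$cyt_CET) *
      caps$Chl / 1000,
    Rubisco_N = res$alloc$n_Etot * caps$N_ps,
    C4_N = res$alloc$n_C4 * caps$N_ps,
    thylakoid_N = res$alloc$n_Jmax * caps$N_ps
  )
  measurement_table(tibble::tibble(
    curve_id = curve_id, x_kind = "none", x_value = NA_real_,
    quantity = names(vals), value = unname(vals), se = NA_real_, n = NA_integer_))
}

#' Normalized squared residuals between predictions and measurements
#'
#' Residuals are expressed as fractions of the experimental mean of the
#' compared set: `r_i = ((pred_i - meas_i) / mean(meas))^2`, where the mean is
#' taken per quantity (quantities have different units, so each is normalized
#' to its own experimental mean). The mean of `r` over all rows is the scan
#' error used in environment inference.
#'
#' @param pred,meas measurement tables (see [measurement_table()]); rows are
#'   matched on `curve_id`, `x_kind`, `x_value` and `quantity`.
#' @return A tibble of matched rows with columns `predicted`, `measured`, `r`.
#' @export
normalized_squared_residuals <- function(pred, meas) {
  pred <- measurement_table(pred)
  meas <- measurement_table(meas)
  key <- c("curve_id", "x_kind", "x_value", "quantity")
  joined <- dplyr::inner_join(
    dplyr::select(pred, dplyr::all_of(key), predicted = "value"),
    dplyr::select(meas, dplyr::all_of(key), measured = "value"),
    by = key)
  if (nrow(joined) != nrow(pred) || nrow(joined) != nrow(meas)) {
    stop("prediction and measurement tables do not match row-for-row",
         call. = FALSE)
  }
  joined <- dplyr::mutate(
    dplyr::group_by(joined, .data$quantity),
    .mean = mean(.data$measured))
  if (any(joined$.mean == 0)) {
    stop("zero experimental mean: residuals cannot be normalized", call. = FALSE)
  }
  joined <- dplyr::ungroup(
    dplyr::mutate(joined, r = ((.data$predicted - .data$measured) / .data$.mean)^2))
  dplyr::select(joined, -".mean")
}

#' Compare the prediction errors of two adaptation scenarios
#'
#' Two-sided Wilcoxon rank-sum test on the normalized squared residual
#' distributions of the two scenarios (exact distribution for combined n of
#' at most 20 without ties, normal approximation with continuity correction
#' otherwise), plus an optional paired sign test for delta_n comparisons
#' across photosynthetic types.
#'
#' @param residuals_evo,residuals_growth numeric residual vectors (or tibbles
#'   from [normalized_squared_residuals()], whose `r` columns are used).
#' @param delta_pairs optional two-column matrix/data frame of paired values
#'   (e.g. delta_n of a C4 type vs a C3 type across conditions) for the sign
#'   test.
#' @return A list with `wilcoxon_p`, `medians`, `n`, and (when `delta_pairs`
#'   is given) `sign_p` and `n_pairs`.
#' @export
compare_scenarios <- function(residuals_evo, residuals_growth,
                              delta_pairs = NULL) {
  getr <- function(x) if (is.data.frame(x)) x$r else as.numeric(x)
  r1 <- getr(residuals_evo)
  r2 <- getr(residuals_growth)
  if (length(r1) < 2 || length(r2) < 2) {
    stop("need at least two residuals per scenario", call. = FALSE)
  }
  exact <- (length(r1) + length(r2)) <= 20 &&
    !any(duplicated(c(r1, r2)))
  wt <- suppressWarnings(stats::wilcox.test(r1, r2, exact = exact,
                                            correct = TRUE))
  out <- list(wilcoxon_p = wt$p.value,
              medians = c(evo = stats::median(r1), growth = stats::median(r2)),
              n = c(evo = length(r1), growth = length(r2)))
  if (!is.null(delta_pairs)) {
    dp <- as.matrix(delta_pairs)
    if (ncol(dp) != 2) stop("delta_pairs must have two columns", call. = FALSE)
    diffs <- dp[, 1] - dp[, 2]
    nz <- diffs[diffs != 0]
    bt <- stats::binom.test(sum(nz > 0), length(nz), p = 0.5)
    out$sign_p <- bt$p.value
    out$n_pairs <- length(nz)
  }
  out
}

#' Simulated gas-exchange response curves
#'
#' Sweeps exactly one environmental axis at a fixed allocation (allocations
#' cannot re-adjust on the timescale of a measurement): an A-Ci curve
#' (intercellular CO2, converted to mesophyll CO2 via the `Cm_over_Ci`
#' diffusion ratio), an A-T curve (leaf temperature), or an A-N curve (total
#' leaf nitrogen).
#'
#' @inheritParams simulate_assimilation
#' @param sweep one of `"Ci"`, `"T"`, `"N"`.
#' @param values sweep values: Ci in ubar, T in degrees C, N_t in mmol m-2.
#' @param curve_id label for the output rows.
#' @return A measurement table with quantity `"A"` and `x_kind` equal to
#'   `sweep`.
#' @export
response_curves <- function(species, env, alloc, partition,
                            sweep = c("Ci", "T", "N"), values,
                            constants = stoichiometry_constants(),
                            tparams = temperature_params(),
                            curve_id = NULL) {
  sweep <- match.arg(sweep)
  stopifnot(is.numeric(values), length(values) >= 1)
  env <- resolve_cm(env, species)
  curve_id <- curve_id %||% paste0("A-", sweep)
  A <- vapply(values, function(x) {
    e <- env
    if (sweep == "Ci") {
      e$C_m <- x * env$Cm_over_Ci
    } else if (sweep == "T") {
      e$T_leaf <- x
      e$T_K <- x + 273.15
    } else {
      e$N_t <- x
    }
    simulate_assimilation(species, e, alloc, partition, constants, tparams)$A
  }, numeric(1))
  measurement_table(tibble::tibble(
    curve_id = curve_id, x_kind = sweep, x_value = values, quantity = "A",
    value = A, se = NA_real_, n = NA_integer_))
}

#' Generate noisy synthetic measurements from model predictions
#'
#' Fixture generator emulating noisy response-curve and pool measurements:
#' model predictions are perturbed by multiplicative Gaussian noise,
#' `value * (1 + eps)` with `eps ~ N(0, noise_sd^2)`, reproducibly under a
#' seed. If no `table` is supplied, the pool quantities of [predict_pools()]
#' are used.
#'
#' @inheritParams predict_pools
#' @param noise_sd relative noise standard deviation (>= 0).
#' @param seed integer seed for reproducibility.
#' @param table optional noiseless measurement table to perturb (any table
#'   from [predict_pools()] or [response_curves()]).
#' @return A measurement table.
#' @export
synthetic_measurements <- function(species = NULL, env = NULL, alloc = NULL,
                                   partition = NULL, noise_sd = 0.05,
                                   seed = 1L, table = NULL,
                                   constants = stoichiometry_constants(),
                                   tparams = temperature_params()) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (is.null(table)) {
    table <- predict_pools(species, env, alloc, partition, constants, tparams)
  }
  table <- measurement_table(table)
  if (noise_sd == 0) return(table)
  rng_state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, envir = globalenv())
  })
  set.seed(seed)
  eps <- stats::rnorm(nrow(table), mean = 0, sd = noise_sd)
  table$value <- table$value * (1 + eps)
  table
}

#' Predicted measurement table for one allocation in one environment
#'
#' Pool quantities (see [predict_pools()]) plus any requested response-curve
#' sweeps at the fixed allocation.
#'
#' @inheritParams predict_pools
#' @param curve_specs list of `list(sweep =, values =)` sweeps, see
#'   [response_curves()].
#' @return A measurement table.
#' @export
cell_predictions <- function(species, env, alloc, partition,
                             curve_specs = NULL,
                             constants = stoichiometry_constants(),
                             tparams = temperature_params()) {
  pred <- predict_pools(species, env, alloc, partition, constants, tparams)
  for (cs in curve_specs) {
    pred <- dplyr::bind_rows(
      pred,
      response_curves(species, env, alloc, partition, sweep = cs$sweep,
                      values = cs$values, constants = constants,
                      tparams = tparams))
  }
  pred
}

#' Precompute optimal-allocation predictions over an environment grid
#'
#' For every `(I, T, C_m)` grid cell, optimizes the allocation and predicts
#' the measurable pool quantities. The result can be reused to score many
#' measurement tables against the same grid (see [environment_scan()]), which
#' keeps replicate analyses cheap.
#'
#' @param species a [species_params()].
#' @param I_values,T_values,Cm_values grid axes (umol quanta m-2 s-1,
#'   degrees C, ubar).
#' @param N_t total leaf nitrogen (mmol m-2), held fixed across the grid.
#' @param O O2 partial pressure (mbar), held fixed across the grid.
#' @param settings optimizer settings for the per-cell optimizations
#'   (default: a reduced budget suitable for grids).
#' @param curve_specs optional list of response-curve sweeps predicted for
#'   every cell in addition to the pool quantities, each a
#'   `list(sweep =, values =)` pair as in [response_curves()] (the allocation
#'   is the cell's optimum; the sweep is run from the cell's environment).
#'   Curves sharpen the fingerprint of each candidate environment.
#' @inheritParams optimize_allocation
#' @return An object of class `photo_scan_grid`: tibble of cells with
#'   list-column `prediction` (measurement tables) and `optim`.
#' @export
scan_predictions <- function(species, I_values, T_values, Cm_values,
                             N_t = 130, O = 200,
                             settings = optimizer_settings(n_starts = 6,
                                                           maxit = 800),
                             curve_specs = NULL,
                             constants = stoichiometry_constants(),
                             tparams = temperature_params()) {
  grid <- tidyr::expand_grid(I = I_values, T_leaf = T_values, C_m = Cm_values)
  cells <- purrr::map(seq_len(nrow(grid)), function(i) {
    env <- environment_spec(I = grid$I[i], T_leaf = grid$T_leaf[i], N_t = N_t,
                            C_m = grid$C_m[i], O = O,
                            label = sprintf("cell_%d", i))
    opt <- tryCatch(
      optimize_allocation(species, env, settings, constants, tparams),
      error = function(e) NULL)
    pred <- if (is.null(opt)) NULL else {
      cell_predictions(species, env, opt$alloc, opt$partition,
                       curve_specs = curve_specs, constants = constants,
                       tparams = tparams)
    }
    list(opt = opt, pred = pred)
  })
  opts <- purrr::map(cells, "opt")
  preds <- purrr::map(cells, "pred")
  structure(dplyr::mutate(grid, prediction = preds, optim = opts,
                          cell = dplyr::row_number()),
            class = c("photo_scan_grid", class(grid)),
            species = species$label, N_t = N_t, O = O)
}

#' Infer the environment that best explains measured data
#'
#' Scores every cell of an environment grid by the mean normalized squared
#' residual between the cell's optimal-allocation predictions and the
#' measured quantities, and returns the full error surface together with the
#' best-fitting (argmin) environment. O2 is held fixed across the grid
#' (atmospheric O2 has been nearly constant on the relevant timescales).
#' Cells whose optimization failed are marked `NA` and excluded from the
#' argmin.
#'
#' @param species a [species_params()]; ignored when `predictions` is given.
#' @param measured a measurement table of observed quantities.
#' @param I_values,T_values,Cm_values grid axes; ignored when `predictions`
#'   is given.
#' @param predictions optional precomputed [scan_predictions()] result.
#' @inheritParams scan_predictions
#' @return An object of class `photo_scan`: list with `surface` (tibble of
#'   `I`, `T_leaf`, `C_m`, `error`), `argmin` (row of the surface),
#'   `residuals_at_argmin`, and the predictions used.
#' @export
environment_scan <- function(species = NULL, measured,
                             I_values = seq(250, 2000, by = 250),
                             T_values = seq(15, 45, by = 5),
                             Cm_values = seq(50, 300, by = 50),
                             predictions = NULL, N_t = 130, O = 200,
                             settings = optimizer_settings(n_starts = 6,
                                                           maxit = 800),
                             constants = stoichiometry_constants(),
                             tparams = temperature_params()) {
  measured <- measurement_table(measured)
  # quantities with a zero experimental mean (structurally absent pools,
  # e.g. C4_N in a C3 plant) cannot be normalized and are excluded
  q_mean <- tapply(measured$value, measured$quantity, mean)
  measured <- measured[measured$quantity %in% names(q_mean)[q_mean != 0], ]
  if (nrow(measured) == 0) stop("no nonzero measured quantities to score", call. = FALSE)
  if (is.null(predictions)) {
    predictions <- scan_predictions(species, I_values, T_values, Cm_values,
                                    N_t = N_t, O = O, settings = settings,
                                    constants = constants, tparams = tparams)
  }
  stopifnot(inherits(predictions, "photo_scan_grid"))
  errors <- vapply(seq_len(nrow(predictions)), function(i) {
    pred <- predictions$prediction[[i]]
    if (is.null(pred)) return(NA_real_)
    # compare only the quantities present in the measurements
    pred <- pred[pred$quantity %in% measured$quantity, ]
    res <- tryCatch(normalized_squared_residuals(pred, measured),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else mean(res$r)
  }, numeric(1))
  surface <- tibble::tibble(I = predictions$I, T_leaf = predictions$T_leaf,
                            C_m = predictions$C_m, error = errors)
  if (all(is.na(errors))) stop("no grid cell could be scored", call. = FALSE)
  if (any(is.na(errors))) {
    warning(sum(is.na(errors)), " grid cell(s) failed and were excluded")
  }
  best <- which.min(errors)
  pred_best <- predictions$prediction[[best]]
  pred_best <- pred_best[pred_best$quantity %in% measured$quantity, ]
  structure(list(surface = surface, argmin = surface[best, ],
                 argmin_cell = best,
                 residuals_at_argmin = normalized_squared_residuals(pred_best,
                                                                    measured),
                 predictions = predictions),
            class = "photo_scan")
}

#' @export
print.photo_scan <- function(x, ...) {
  cat("<photo_scan> ", nrow(x$surface), " cells\n", sep = "")
  cat("  argmin: I = ", x$argmin$I, ", T = ", x$argmin$T_leaf, " C, C_m = ",
      x$argmin$C_m, " ubar (error = ", signif(x$argmin$error, 4), ")\n", sep = "")
  invisible(x)
}
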