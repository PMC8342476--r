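#' Irradiance absorbed by each electron-transport chain
#'
#' Incident light is discounted by leaf absorptance and spectral quality and
#' split between the chains according to the LET proportion `p`. The linear
#' chain shares its quanta equally between PSI and PSII (factor 0.5); the
#' cyclic chain delivers its full share to PSI:
#' `I_LET = I * alpha * (1 - f) * p * 0.5`,
#' `I_CET = I * alpha * (1 - f) * (1 - p)`.
#'
#' @param I incident irradiance (umol quanta m-2 s-1).
#' @param p proportion of linear electron transport.
#' @param constants see [stoichiometry_constants()].
#' @return List with `I_LET` and `I_CET` (umol quanta m-2 s-1).
#' @export
absorbed_irradiance <- function(I, p, constants = stoichiometry_constants()) {
  .check_scalar(I, "I", lower = 0)
  .check_scalar(p, "p", 0, 1)
  base <- I * constants$alpha * (1 - constants$f)
  list(I_LET = base * p * 0.5, I_CET = base * (1 - p))
}

#' Realized electron transport from absorbed light
#'
#' Non-rectangular hyperbola between absorbed irradiance and electron
#' transport: the smaller root of
#' `Theta J^2 - (I_abso + Jmax) J + I_abso Jmax = 0`, which saturates at
#' `Jmax` and has unit initial slope in `I_abso`.
#'
#' @param I_abso absorbed irradiance reaching the chain (umol quanta m-2 s-1).
#' @param Jmax maximal electron transport rate (umol e- m-2 s-1).
#' @param Theta convexity of the hyperbola, in `(0, 1]`.
#' @return Electron transport rate J (umol e- m-2 s-1).
#' @examples
#' electron_transport(100, 200, 0.7)  # (300 - sqrt(34000)) / 1.4
#' @export
electron_transport <- function(I_abso, Jmax, Theta = 0.7) {
  .check_scalar(I_abso, "I_abso", lower = 0)
  .check_scalar(Jmax, "Jmax", lower = 0)
  .check_scalar(Theta, "Theta", lower = 1e-12, upper = 1)
  if (I_abso == 0 || Jmax == 0) return(0)
  s <- I_abso + Jmax
  disc <- s * s - 4 * Theta * I_abso * Jmax
  # Theta <= 1 guarantees disc >= (I - Jmax)^2 >= 0
  stopifnot(disc >= 0)
  (s - sqrt(disc)) / (2 * Theta)
}

#' ATP and NADPH supply from the two electron-transport chains
#'
#' NADPH is produced by the linear chain only (2 e- per NADPH):
#' `nadph_rate = J_LET / 2`. ATP is produced by both chains:
#' the linear chain yields `J_LET / e_ATP` (e_ATP = 4/3 electrons per ATP with
#' an active Q-cycle), the cyclic chain pumps 2 H+ per electron, giving
#' `J_CET * 2 / h_per_atp` ATP with `h_per_atp` protons per ATP (default 4).
#'
#' @param J_LET,J_CET realized electron transport rates (umol e- m-2 s-1).
#' @param constants see [stoichiometry_constants()].
#' @return List with `atp_rate` and `nadph_rate` (umol m-2 s-1).
#' @export
energy_supply <- function(J_LET, J_CET, constants = stoichiometry_constants()) {
  .check_scalar(J_LET, "J_LET", lower = 0)
  .check_scalar(J_CET, "J_CET", lower = 0)
  list(atp_rate = J_LET / constants$e_ATP + J_CET * 2 / constants$h_per_atp,
       nadph_rate = J_LET / 2)
}

#' Energy partition across the five consuming processes
#'
#' The available energy is partitioned between the Calvin-Benson cycle in the
#' mesophyll (`f_cb_m`) and bundle sheath (`f_cb_s`), the photorespiratory
#' pathway in the two compartments (`f_pr_m`, `f_pr_s`) and the C4 cycle
#' (`f_c4`). Fractions are non-negative and sum to one; they are decision
#' variables of the optimizer, not closed-form splits.
#'
#' @param f_cb_m,f_pr_m,f_cb_s,f_pr_s,f_c4 energy fractions.
#' @return An object of class `photo_partition`.
#' @export
energy_partition <- function(f_cb_m, f_pr_m = 0, f_cb_s = 0, f_pr_s = 0,
                             f_c4 = 0) {
  f <- c(f_cb_m = f_cb_m, f_pr_m = f_pr_m, f_cb_s = f_cb_s, f_pr_s = f_pr_s,
         f_c4 = f_c4)
  if (any(!is.finite(f)) || any(f < -1e-12)) {
    stop("energy fractions must be non-negative", call. = FALSE)
  }
  f <- pmax(f, 0)
  if (abs(sum(f) - 1) > 1e-9) {
    stop("energy fractions must sum to 1 (got ", format(sum(f), digits = 12),
         ")", call. = FALSE)
  }
  structure(as.list(f), class = "photo_partition")
}

#' @export
print.photo_partition <- function(x, ...) {
  cat("<photo_partition> ",
      paste(names(unclass(x)), signif(unlist(x), 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Aggregate electron-transport pools from an energy partition
#'
#' Bookkeeping aggregates of the five-pool partition over total electron
#' transport `J_t`: `J_mc` (mesophyll Calvin-Benson + photorespiration),
#' `J_s` (bundle-sheath Calvin-Benson + photorespiration) and `J_mp` (C4
#' cycle). Their sum is `J_t`.
#'
#' @param J_t total electron transport (umol e- m-2 s-1).
#' @param partition an [energy_partition()].
#' @return List with `J_mc`, `J_mp`, `J_s`.
#' @export
partition_energy <- function(J_t, partition) {
  .check_scalar(J_t, "J_t", lower = 0)
  stopifnot(inherits(partition, "photo_partition"))
  list(J_mc = (partition$f_cb_m + partition$f_pr_m) * J_t,
       J_mp = partition$f_c4 * J_t,
       J_s = (partition$f_cb_s + partition$f_pr_s) * J_t)
}
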