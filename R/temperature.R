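#' Peaked Arrhenius temperature response
#'
#' Extended Arrhenius function combining the exponential rate increase with
#' temperature (activation energy `E`) and enzyme inactivation through thermal
#' instability (deactivation energy `H` and entropy factor `S`):
#' \deqn{f(T) = k_{25} \exp\!\left[E \frac{T - 298.15}{298.15\,R\,T}\right]
#'   \frac{1 + \exp\!\left(\frac{298.15 S - H}{298.15 R}\right)}
#'        {1 + \exp\!\left(\frac{T S - H}{T R}\right)}}
#' At 298.15 K the function returns `k25` exactly for any `(E, H, S)`. A
#' quantity with no deactivation uses the sentinel `H = Inf` (with `S = 0`),
#' which reduces the expression to a plain Arrhenius curve. Exponential
#' arguments are clamped to avoid overflow; the result is always positive and
#' never NaN.
#'
#' @param T_K temperature (K).
#' @param k25 value at 25 C (native units).
#' @param E activation energy (J mol-1).
#' @param H deactivation energy (J mol-1), `Inf` for no deactivation.
#' @param S entropy factor (J mol-1 K-1).
#' @param R gas constant (J mol-1 K-1).
#' @return The temperature-scaled value (same units as `k25`).
#' @examples
#' arrhenius_extended(298.15, k25 = 10, E = 65000, H = 150000, S = 490)  # 10
#' @export
arrhenius_extended <- function(T_K, k25, E, H = Inf, S = 0, R = 8.314) {
  if (any(T_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  clamp <- function(x) pmin(pmax(x, -700), 700)
  arr <- exp(clamp(E * (T_K - 298.15) / (298.15 * R * T_K)))
  if (is.infinite(H)) {
    peak <- 1
  } else {
    num <- 1 + exp(clamp((298.15 * S - H) / (298.15 * R)))
    den <- 1 + exp(clamp((T_K * S - H) / (T_K * R)))
    peak <- num / den
  }
  k25 * arr * peak
}

#' Default temperature-response parameter set
#'
#' One `(E, H, S)` triplet per temperature-dependent quantity, applied as a
#' multiplier curve (`k25 = 1`) to the 25 C capacities and kinetic constants.
#' Shipped defaults are standard literature values: peaked responses for the
#' C4-cycle capacity, Rubisco turnover and the electron-transport capacities
#' (Massad-type parameters), plain Arrhenius for the Michaelis constants
#' (Bernacchi-type activation energies), and a declining curve for Rubisco
#' specificity (negative activation energy, mirroring the rise of the CO2
#' compensation point with temperature). All values are config-overridable;
#' quantities omitted from the set pass through unscaled.
#'
#' @param ... named overrides; each a list with elements `E`, `H`, `S`.
#' @return An object of class `photo_tparams`: named list of
#'   `list(E, H, S)` entries for `V_pmax`, `k_ccat`, `J_max`, `K_p`, `K_c`,
#'   `K_o`, `S_co`.
#' @export
temperature_params <- function(...) {
  defaults <- list(
    V_pmax = list(E = 94800, H = 73300, S = 250),
    k_ccat = list(E = 67294, H = 144568, S = 472),
    J_max  = list(E = 77900, H = 191929, S = 627),
    K_p    = list(E = 36300, H = Inf, S = 0),
    K_c    = list(E = 79430, H = Inf, S = 0),
    K_o    = list(E = 36380, H = Inf, S = 0),
    S_co   = list(E = -37830, H = Inf, S = 0)
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown temperature quantity(ies): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(overrides)) {
      entry <- overrides[[nm]]
      if (!is.list(entry) || !all(c("E", "H", "S") %in% names(entry))) {
        stop("temperature entry ", nm, " must be list(E=, H=, S=)", call. = FALSE)
      }
      if (entry$H < 0) stop("deactivation energy H must be >= 0", call. = FALSE)
      defaults[[nm]] <- entry[c("E", "H", "S")]
    }
  }
  structure(defaults, class = "photo_tparams")
}

# multiplier f(T)/k25 for one named quantity; 1 if absent from the set
.t_scale <- function(tparams, quantity, T_K) {
  entry <- tparams[[quantity]]
  if (is.null(entry)) return(1)
  arrhenius_extended(T_K, 1, entry$E, entry$H, entry$S)
}

#' Apply temperature scaling to capacities and kinetic constants
#'
#' Scales each temperature-dependent quantity by its own peaked-Arrhenius
#' multiplier: the C4-cycle capacity, the Rubisco turnover, the two maximal
#' electron-transport rates (shared `J_max` curve), and the kinetic constants
#' `K_p`, `K_c`, `K_o` and the Rubisco specificity. Quantities without an
#' entry in `tparams` pass through unchanged; at 25 C the mapping is the
#' identity.
#'
#' @param caps a [capacities()] object (25 C reference values).
#' @param species a [species_params()] (supplies 25 C kinetics).
#' @param env an [environment_spec()] (supplies temperature).
#' @param tparams a [temperature_params()] set.
#' @return List of temperature-adjusted values: `V_pmax`, `k_ccat`, `V_cmax`
#'   (= `E_tot * k_ccat(T)`), `Jmax_LET`, `Jmax_CET`, `K_p`, `K_c`, `K_o`,
#'   `S_co`.
#' @export
apply_temperature <- function(caps, species, env,
                              tparams = temperature_params()) {
  stopifnot(inherits(caps, "photo_capacities"), inherits(env, "photo_env"))
  T_K <- env$T_K
  kcat_T <- species$k_ccat * .t_scale(tparams, "k_ccat", T_K)
  jscale <- .t_scale(tparams, "J_max", T_K)
  list(
    V_pmax = caps$V_pmax * .t_scale(tparams, "V_pmax", T_K),
    k_ccat = kcat_T,
    V_cmax = caps$E_tot * kcat_T,
    Jmax_LET = caps$Jmax_LET * jscale,
    Jmax_CET = caps$Jmax_CET * jscale,
    K_p = species$K_p * .t_scale(tparams, "K_p", T_K),
    K_c = species$K_c25 * .t_scale(tparams, "K_c", T_K),
    K_o = species$K_o25 * .t_scale(tparams, "K_o", T_K),
    S_co = species$S_co25 * .t_scale(tparams, "S_co", T_K)
  )
}
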