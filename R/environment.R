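#' Specify a simulation environment
#'
#' An environment is described by incident irradiance, leaf temperature,
#' mesophyll CO2 partial pressure, O2 partial pressure and total leaf nitrogen.
#' The mesophyll CO2 level may be given directly (`C_m`), or derived from an
#' atmospheric CO2 level `C_a` together with the `C_a`/`C_i` ratio and the
#' `C_m`/`C_i` diffusion ratio (see [derive_cm()]). When `C_a` is supplied and
#' `Ca_over_Ci` is left `NULL`, a photosynthetic-type default ratio is applied
#' when the environment is resolved against a species (see [resolve_cm()]).
#'
#' @param I incident irradiance (umol quanta m-2 s-1).
#' @param T_leaf leaf temperature (degrees C).
#' @param N_t total leaf nitrogen (mmol m-2).
#' @param C_m mesophyll CO2 partial pressure (ubar), or `NULL` to derive from `C_a`.
#' @param C_a atmospheric CO2 partial pressure (ubar), optional.
#' @param Ca_over_Ci ratio of atmospheric to intercellular CO2 (>= 1), optional.
#' @param Cm_over_Ci ratio of mesophyll to intercellular CO2 (<= 1, default 0.85).
#' @param O O2 partial pressure (mbar, default 210 = current atmosphere).
#' @param label optional name.
#' @return An object of class `photo_env`.
#' @examples
#' environment_spec(I = 1500, T_leaf = 30, N_t = 130, C_a = 280, O = 200)
#' @export
environment_spec <- function(I, T_leaf, N_t, C_m = NULL, C_a = NULL,
                             Ca_over_Ci = NULL, Cm_over_Ci = 0.85, O = 210,
                             label = NULL) {
  .check_scalar(I, "I", lower = 0)
  .check_scalar(T_leaf, "T_leaf", lower = -273.15)
  .check_scalar(N_t, "N_t", lower = 0)
  .check_scalar(O, "O", lower = 0)
  if (is.null(C_m) && is.null(C_a)) {
    stop("one of C_m or C_a must be given", call. = FALSE)
  }
  if (!is.null(C_m)) .check_scalar(C_m, "C_m", lower = 0)
  if (!is.null(C_a)) .check_scalar(C_a, "C_a", lower = 0)
  if (!is.null(Ca_over_Ci)) .check_scalar(Ca_over_Ci, "Ca_over_Ci", lower = 1)
  .check_scalar(Cm_over_Ci, "Cm_over_Ci", lower = 0, upper = 1)
  if (!is.null(C_m) && !is.null(C_a) && C_m >= C_a) {
    stop("C_m must be below C_a (CO2 enters the mesophyll through diffusion)",
         call. = FALSE)
  }
  structure(list(I = I, T_leaf = T_leaf, T_K = T_leaf + 273.15, N_t = N_t,
                 C_m = C_m, C_a = C_a, Ca_over_Ci = Ca_over_Ci,
                 Cm_over_Ci = Cm_over_Ci, O = O,
                 label = label %||% "environment"),
            class = "photo_env")
}

#' @export
print.photo_env <- function(x, ...) {
  cat("<photo_env> ", x$label, "\n", sep = "")
  cat("  I = ", x$I, " umol m-2 s-1, T = ", x$T_leaf, " C, N_t = ", x$N_t,
      " mmol m-2\n", sep = "")
  if (!is.null(x$C_m)) cat("  C_m = ", x$C_m, " ubar", sep = "")
  if (!is.null(x$C_a)) cat("  C_a = ", x$C_a, " ubar", sep = "")
  cat(", O = ", x$O, " mbar\n", sep = "")
  invisible(x)
}

#' Derive mesophyll CO2 from atmospheric CO2
#'
#' `C_m = C_a / Ca_over_Ci * Cm_over_Ci`. CO2 reaches the mesophyll by
#' diffusion through stomata and the cell wall, so both conversion steps can
#' only lower the partial pressure: `Ca_over_Ci >= 1` and `Cm_over_Ci <= 1`
#' (default 0.85).
#'
#' @param C_a atmospheric CO2 partial pressure (ubar).
#' @param Ca_over_Ci ratio of atmospheric to intercellular CO2.
#' @param Cm_over_Ci ratio of mesophyll to intercellular CO2.
#' @return Mesophyll CO2 partial pressure (ubar).
#' @examples
#' derive_cm(280, 2, 0.85)  # 119
#' @export
derive_cm <- function(C_a, Ca_over_Ci, Cm_over_Ci = 0.85) {
  .check_scalar(C_a, "C_a", lower = 0)
  if (!is.numeric(Ca_over_Ci) || Ca_over_Ci <= 0) {
    stop("Ca_over_Ci must be positive", call. = FALSE)
  }
  if (Ca_over_Ci < 1) {
    stop("Ca_over_Ci must be >= 1: intercellular CO2 cannot exceed atmospheric CO2",
         call. = FALSE)
  }
  if (!is.numeric(Cm_over_Ci) || Cm_over_Ci <= 0) {
    stop("Cm_over_Ci must be positive", call. = FALSE)
  }
  if (Cm_over_Ci > 1) {
    stop("Cm_over_Ci must be <= 1: CO2 enters the mesophyll through diffusion",
         call. = FALSE)
  }
  C_a / Ca_over_Ci * Cm_over_Ci
}

#' Resolve the mesophyll CO2 level of an environment for a species
#'
#' If the environment specifies `C_m` directly it is returned as-is. Otherwise
#' `C_m` is derived from `C_a` using the environment's `Ca_over_Ci` when given,
#' or the species' photosynthetic-type default drawdown ratio (C4 plants run
#' lower intercellular CO2 than C3 plants because of their CO2 pump).
#'
#' @param env a [environment_spec()] object.
#' @param species a [species_params()] object.
#' @return The environment with `C_m` filled in (ubar).
#' @export
resolve_cm <- function(env, species) {
  stopifnot(inherits(env, "photo_env"))
  if (!is.null(env$C_m)) return(env)
  ratio <- env$Ca_over_Ci %||% species$Ca_over_Ci
  env$C_m <- derive_cm(env$C_a, ratio, env$Cm_over_Ci)
  env
}

#' Built-in environment presets
#'
#' Named environments used throughout the analyses: the putative evolutionary
#' environment of the C4 lineages (high light, warm, pre-industrial 280 ubar
#' atmospheric CO2, 200 mbar O2) and the growth conditions of the three
#' experimental studies the model is compared against (A-Ci/A-T study,
#' leaf-nitrogen study, and the resource-allocation study at two growth
#' temperatures). The evolutionary-scenario irradiance of 1500 umol quanta
#' m-2 s-1 is a stated package assumption ("high light"); all fields can be
#' overridden via the YAML configuration.
#'
#' @param N_t total leaf nitrogen (mmol m-2) stamped on every preset (default 130).
#' @return Named list of `photo_env` objects.
#' @export
environment_presets <- function(N_t = 130) {
  list(
    evolutionary = environment_spec(
      I = 1500, T_leaf = 30, N_t = N_t, C_a = 280, O = 200,
      label = "evolutionary"),
    growth_aci = environment_spec(
      I = 560, T_leaf = 37, N_t = N_t, C_a = 380, O = 210,
      label = "growth_aci"),
    growth_nitrogen = environment_spec(
      I = 554, T_leaf = 30, N_t = N_t, C_a = 380, O = 210,
      label = "growth_nitrogen"),
    growth_alloc_25 = environment_spec(
      I = 550, T_leaf = 25, N_t = N_t, C_a = 380, O = 210,
      label = "growth_alloc_25"),
    growth_alloc_35 = environment_spec(
      I = 550, T_leaf = 35, N_t = N_t, C_a = 380, O = 210,
      label = "growth_alloc_35")
  )
}

#' Convert in vitro PEPC activity to an in vivo estimate
#'
#' Measured in vitro PEPC activities overestimate the activity realized in the
#' leaf; the standard correction divides the in vitro value by 3.
#'
#' @param v_invitro in vitro activity (umol m-2 s-1).
#' @return in vivo activity (umol m-2 s-1).
#' @examples
#' pepc_invitro_to_invivo(300)  # 100
#' @export
pepc_invitro_to_invivo <- function(v_invitro) {
  if (!is.numeric(v_invitro) || any(is.na(v_invitro)) || any(v_invitro < 0)) {
    stop("in vitro PEPC activity must be non-negative", call. = FALSE)
  }
  v_invitro / 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
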