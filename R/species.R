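#' Rubisco kinetic trade-off
#'
#' Rubisco kinetics are specified through the single turnover parameter
#' `k_ccat`; the Michaelis constant for CO2 and the CO2/O2 specificity follow
#' from the known catalytic trade-off (faster Rubiscos are less CO2-affine and
#' less specific). The shipped form is a pair of power laws anchored at a
#' typical C3 Rubisco (kcat 3.5 s-1, K_c 650 ubar, K_o 450 mbar, specificity
#' 2590 on a partial-pressure basis):
#' `K_c = Kc_ref * (kcat/kcat_ref)^exp_Kc` and
#' `S = S_ref * (kcat/kcat_ref)^exp_S`, with `K_o` held constant.
#' Exponents and anchors are configurable.
#'
#' @param kcat_ref,Kc_ref,Ko_ref,S_ref anchor values (s-1, ubar, mbar, unitless).
#' @param exp_Kc,exp_S power-law exponents.
#' @return A `rubisco_tradeoff` list.
#' @export
rubisco_tradeoff <- function(kcat_ref = 3.5, Kc_ref = 650, Ko_ref = 450,
                             S_ref = 2590, exp_Kc = 2, exp_S = -0.5) {
  structure(list(kcat_ref = kcat_ref, Kc_ref = Kc_ref, Ko_ref = Ko_ref,
                 S_ref = S_ref, exp_Kc = exp_Kc, exp_S = exp_S),
            class = "rubisco_tradeoff")
}

#' Derive Rubisco kinetic parameters from the turnover rate
#'
#' @param k_ccat Rubisco carboxylation turnover (s-1).
#' @param tradeoff a [rubisco_tradeoff()] object.
#' @return List with `K_c25` (ubar), `K_o25` (mbar), `S_co25` (specificity,
#'   partial-pressure basis) at 25 C.
#' @export
rubisco_kinetics <- function(k_ccat, tradeoff = rubisco_tradeoff()) {
  .check_scalar(k_ccat, "k_ccat", lower = 1e-9)
  rel <- k_ccat / tradeoff$kcat_ref
  list(K_c25 = tradeoff$Kc_ref * rel^tradeoff$exp_Kc,
       K_o25 = tradeoff$Ko_ref,
       S_co25 = tradeoff$S_ref * rel^tradeoff$exp_S)
}

.PTYPES <- c("C3", "C3-C4", "C4-like", "C4")

#' Define a photosynthetic type
#'
#' A species (or photosynthetic archetype) is defined by six parameters: the
#' Rubisco distribution between mesophyll and bundle sheath (`beta`, fraction
#' of Rubisco in the bundle sheath; 0 in C3 plants), the Rubisco turnover
#' `k_ccat` (dependent kinetics via [rubisco_kinetics()]), the fraction `xi` of
#' bundle-sheath glycine decarboxylation fed by mesophyll oxygenation (the
#' C3-C4 glycine shuttle), the PEPC Michaelis constant for bicarbonate `K_p`,
#' and the bundle-sheath CO2 leak conductance `g_s`. Allocation bounds restrict
#' the nitrogen fractions per pool; C3 types must have a zero upper bound on
#' the C4-cycle pool.
#'
#' @param label species name.
#' @param ptype one of `"C3"`, `"C3-C4"`, `"C4-like"`, `"C4"`.
#' @param beta fraction of Rubisco in the bundle sheath, in `[0, 1]`.
#' @param k_ccat Rubisco turnover (s-1).
#' @param xi glycine-shuttle fraction, in `[0, 1]`.
#' @param K_p PEPC Michaelis constant for bicarbonate (ubar).
#' @param g_s bundle-sheath CO2 conductance (umol m-2 s-1 ubar-1).
#' @param allocation_bounds list with elements `n_Etot`, `n_C4`, `n_Jmax`, `p`,
#'   each a `c(lower, upper)` pair of fractions.
#' @param Ca_over_Ci default atmospheric-to-intercellular CO2 ratio used when
#'   an environment specifies only `C_a` (C4 plants draw down further).
#' @param tradeoff Rubisco kinetic trade-off, see [rubisco_tradeoff()].
#' @param n_rubisco,n_fit optional empirical C3 baseline fractions, carried for
#'   reporting only.
#' @return An object of class `photo_species`.
#' @export
species_params <- function(label, ptype, beta, k_ccat, xi, K_p, g_s,
                           allocation_bounds = NULL, Ca_over_Ci = NULL,
                           tradeoff = rubisco_tradeoff(),
                           n_rubisco = NULL, n_fit = NULL) {
  ptype <- match.arg(ptype, .PTYPES)
  .check_scalar(beta, "beta", 0, 1)
  .check_scalar(xi, "xi", 0, 1)
  .check_scalar(k_ccat, "k_ccat", lower = 1e-12)
  .check_scalar(K_p, "K_p", lower = 1e-12)
  .check_scalar(g_s, "g_s", lower = 1e-12)
  default_bounds <- list(n_Etot = c(0, 1), n_C4 = c(0, 1), n_Jmax = c(0, 1),
                         p = c(0, 1))
  if (ptype == "C3") default_bounds$n_C4 <- c(0, 0)
  bounds <- utils::modifyList(default_bounds, allocation_bounds %||% list())
  unknown <- setdiff(names(bounds), names(default_bounds))
  if (length(unknown)) {
    stop("unknown allocation bound(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (!is.numeric(b) || length(b) != 2 || any(is.na(b)) || b[1] > b[2] ||
        b[1] < 0 || b[2] > 1) {
      stop("allocation bound ", nm, " must be c(lower, upper) within [0, 1]",
           call. = FALSE)
    }
  }
  if (ptype == "C3" && bounds$n_C4[2] > 0) {
    stop("C3 species cannot invest nitrogen into the C4 cycle: upper bound on ",
         "n_C4 must be 0", call. = FALSE)
  }
  kin <- rubisco_kinetics(k_ccat, tradeoff)
  structure(list(label = label, ptype = ptype, beta = beta, k_ccat = k_ccat,
                 xi = xi, K_p = K_p, g_s = g_s,
                 allocation_bounds = bounds,
                 Ca_over_Ci = Ca_over_Ci %||%
                   (if (ptype %in% c("C4", "C4-like")) 1 / 0.4 else 1 / 0.7),
                 K_c25 = kin$K_c25, K_o25 = kin$K_o25, S_co25 = kin$S_co25,
                 tradeoff = tradeoff,
                 n_rubisco = n_rubisco, n_fit = n_fit),
            class = "photo_species")
}

#' @export
print.photo_species <- function(x, ...) {
  cat("<photo_species> ", x$label, " (", x$ptype, ")\n", sep = "")
  cat("  beta = ", x$beta, ", k_ccat = ", x$k_ccat, " s-1, xi = ", x$xi,
      ", K_p = ", x$K_p, " ubar, g_s = ", x$g_s, " umol m-2 s-1 ubar-1\n",
      sep = "")
  cat("  derived 25C kinetics: K_c = ", signif(x$K_c25, 4), " ubar, K_o = ",
      signif(x$K_o25, 4), " mbar, S_c/o = ", signif(x$S_co25, 4), "\n", sep = "")
  invisible(x)
}

#' Built-in photosynthetic-type archetypes
#'
#' Four archetypes spanning the C3-to-C4 trajectory of the genus *Flaveria*:
#' a C3 species (all Rubisco in the mesophyll, no C4 cycle), a C3-C4
#' intermediate (glycine shuttle active, partial bundle-sheath Rubisco, a small
#' permitted C4 cycle), a C4-like species and a full C4 species (Rubisco
#' concentrated in the bundle sheath, faster and less specific Rubisco, tight
#' bundle sheath). Parameter values are provisional literature-typical values
#' (the trajectory endpoints follow standard C4-model parameterizations:
#' K_p = 80 ubar, g_s = 0.003 umol m-2 s-1 ubar-1, C3 Rubisco kcat 3.5 s-1
#' rising to 5.44 s-1 in C4), not transcriptions of any specific measured
#' species, and are fully overridable via configuration.
#'
#' @return Named list of `photo_species` objects
#'   (`C3`, `C3-C4`, `C4-like`, `C4`).
#' @export
species_archetypes <- function() {
  list(
    "C3" = species_params(
      label = "C3 archetype", ptype = "C3",
      beta = 0, k_ccat = 3.5, xi = 0, K_p = 80, g_s = 0.003,
      n_rubisco = 0.25, n_fit = 0.25),
    "C3-C4" = species_params(
      label = "C3-C4 archetype", ptype = "C3-C4",
      beta = 0.5, k_ccat = 3.8, xi = 1, K_p = 80, g_s = 0.003,
      allocation_bounds = list(n_C4 = c(0, 0.05))),
    "C4-like" = species_params(
      label = "C4-like archetype", ptype = "C4-like",
      beta = 0.85, k_ccat = 5.0, xi = 1, K_p = 80, g_s = 0.003),
    "C4" = species_params(
      label = "C4 archetype", ptype = "C4",
      beta = 0.95, k_ccat = 5.44, xi = 1, K_p = 80, g_s = 0.003)
  )
}
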