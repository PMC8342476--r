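#' Nitrogen allocation across the photosynthetic pools
#'
#' The photosynthetic nitrogen pool is split between Rubisco (`n_Etot`), the
#' C4-cycle enzymes PEPC and PPDK (`n_C4`) and the thylakoids (`n_Jmax`); the
#' fractions must sum to one. `p` is the proportion of the thylakoid machinery
#' wired for linear electron transport (the rest runs the cyclic chain).
#'
#' @param n_Etot,n_C4,n_Jmax nitrogen fractions, each in `[0, 1]`, summing to 1
#'   within `1e-9`.
#' @param p proportion of linear electron transport, in `[0, 1]`.
#' @param scenario optional tag (e.g. `"evolutionary"`, `"growth"`).
#' @return An object of class `photo_allocation`.
#' @examples
#' allocation(0.45, 0.05, 0.5, p = 0.9)
#' @export
allocation <- function(n_Etot, n_C4, n_Jmax, p, scenario = NULL) {
  .check_scalar(n_Etot, "n_Etot", 0, 1)
  .check_scalar(n_C4, "n_C4", 0, 1)
  .check_scalar(n_Jmax, "n_Jmax", 0, 1)
  .check_scalar(p, "p", 0, 1)
  s <- n_Etot + n_C4 + n_Jmax
  if (abs(s - 1) > 1e-9) {
    stop("nitrogen fractions must sum to 1 (got ", format(s, digits = 12), ")",
         call. = FALSE)
  }
  structure(list(n_Etot = n_Etot, n_C4 = n_C4, n_Jmax = n_Jmax, p = p,
                 scenario = scenario),
            class = "photo_allocation")
}

#' @export
print.photo_allocation <- function(x, ...) {
  cat("<photo_allocation>", if (!is.null(x$scenario)) paste0("[", x$scenario, "]"),
      "\n  n_Etot = ", signif(x$n_Etot, 4), ", n_C4 = ", signif(x$n_C4, 4),
      ", n_Jmax = ", signif(x$n_Jmax, 4), ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Photosynthetic nitrogen available from total leaf nitrogen
#'
#' Maps total leaf nitrogen (mmol m-2) to the photosynthetic nitrogen pool
#' (umol m-2). The shipped map is linear, `N_ps = fraction * N_t * 1000`, with
#' the fraction taken from the constants (`N_ps_fraction`, default 0.75); a
#' custom monotone map can be supplied through `fun`.
#'
#' @param N_t total leaf nitrogen (mmol m-2).
#' @param constants see [stoichiometry_constants()].
#' @param fun optional function `N_t (mmol) -> N_ps (umol)`; must satisfy
#'   `fun(0) == 0` and be non-decreasing.
#' @return Photosynthetic nitrogen (umol m-2).
#' @export
photosynthetic_nitrogen <- function(N_t, constants = stoichiometry_constants(),
                                    fun = NULL) {
  if (!is.numeric(N_t) || any(is.na(N_t)) || any(N_t < 0)) {
    stop("N_t must be non-negative", call. = FALSE)
  }
  if (!is.null(fun)) return(fun(N_t))
  constants$N_ps_fraction * N_t * 1000
}

#' Rubisco catalytic sites from the Rubisco nitrogen pool
#'
#' `E_tot = n_Etot * N_ps * c_E` with `c_E` the number of catalytic sites per
#' unit nitrogen (1.27e-3 umol sites per umol N).
#'
#' @param n_Etot fraction of photosynthetic nitrogen invested in Rubisco.
#' @param N_ps photosynthetic nitrogen (umol m-2).
#' @param constants see [stoichiometry_constants()].
#' @return Rubisco catalytic sites (umol m-2).
#' @export
rubisco_sites <- function(n_Etot, N_ps, constants = stoichiometry_constants()) {
  .check_scalar(n_Etot, "n_Etot", 0, 1)
  .check_scalar(N_ps, "N_ps", lower = 0)
  n_Etot * N_ps * constants$c_E
}

#' Maximal C4-cycle activity from the C4 nitrogen pool
#'
#' PEPC and PPDK co-limit the C4 cycle; the nitrogen cost per unit of maximal
#' activity is the sum of their nitrogen-per-site over turnover ratios:
#' `V_pmax = n_C4 * N_ps / (MW*_PPDK / kcat_PPDK + MW*_PEPC / kcat_PEPC)` where
#' `MW* = protein_N_fraction * MW / 14` converts a molecular weight (Da) to
#' umol nitrogen per umol catalytic site (14 g mol-1 nitrogen).
#'
#' @inheritParams rubisco_sites
#' @param n_C4 fraction of photosynthetic nitrogen invested in PEPC + PPDK.
#' @return Maximal C4-cycle activity (umol m-2 s-1).
#' @export
c4_capacity <- function(n_C4, N_ps, constants = stoichiometry_constants()) {
  .check_scalar(n_C4, "n_C4", 0, 1)
  .check_scalar(N_ps, "N_ps", lower = 0)
  mw_star <- function(mw) constants$protein_N_fraction * mw / 14
  denom <- mw_star(constants$MW_PPDK) / constants$kcat_PPDK +
    mw_star(constants$MW_PEPC) / constants$kcat_PEPC
  n_C4 * N_ps / denom
}

#' Chlorophyll content from the thylakoid nitrogen pool
#'
#' Chlorophyll is taken proportional to thylakoid nitrogen via the empirical
#' factor `n_Chl`: `Chl = n_Chl * n_Jmax * N_ps`.
#'
#' @inheritParams rubisco_sites
#' @param n_Jmax fraction of photosynthetic nitrogen invested in thylakoids.
#' @param fun optional alternative map `(n_Jmax * N_ps) -> Chl`.
#' @return Chlorophyll (umol m-2).
#' @export
chlorophyll_content <- function(n_Jmax, N_ps,
                                constants = stoichiometry_constants(),
                                fun = NULL) {
  .check_scalar(n_Jmax, "n_Jmax", 0, 1)
  .check_scalar(N_ps, "N_ps", lower = 0)
  if (!is.null(fun)) return(fun(n_Jmax * N_ps))
  constants$n_Chl * n_Jmax * N_ps
}

#' Partition the photosystems and light-harvesting complexes between chains
#'
#' The chlorophyll pool is shared between PSI, PSII and the LHC, split between
#' the linear chain (fraction `p`, which carries all PSII) and the cyclic chain
#' (fraction `1 - p`, PSI only):
#' `PSI_LET = PSI * p`, `PSI_CET = PSI * (1 - p)`, `PSII` fixed, and LHC
#' abundances absorb the remaining chlorophyll of each share. Negative LHC
#' abundances indicate an infeasible `p` (the photosystems alone would exceed
#' the chain's chlorophyll share).
#'
#' @param p proportion of linear electron transport.
#' @param constants see [stoichiometry_constants()].
#' @param check error on negative LHC abundances (default `TRUE`).
#' @return List with `PSI_LET`, `PSI_CET`, `PSII`, `LHC_LET`, `LHC_CET`
#'   (mmol per mol Chl).
#' @export
thylakoid_split <- function(p, constants = stoichiometry_constants(),
                            check = TRUE) {
  .check_scalar(p, "p", 0, 1)
  PSI_LET <- constants$PSI * p
  PSI_CET <- constants$PSI * (1 - p)
  PSII <- constants$PSII
  LHC_LET <- (1000 * p - PSII * constants$pII_Chl - PSI_LET * constants$pI_Chl) /
    constants$l_Chl
  LHC_CET <- (1000 * (1 - p) - PSI_CET * constants$pI_Chl) / constants$l_Chl
  # round-off guard at the feasibility boundary
  if (LHC_LET < 0 && LHC_LET > -1e-9) LHC_LET <- 0
  if (LHC_CET < 0 && LHC_CET > -1e-9) LHC_CET <- 0
  if (check && (LHC_LET < 0 || LHC_CET < 0)) {
    stop("infeasible LET proportion p = ", signif(p, 6),
         ": negative light-harvesting complex abundance (feasible p >= ",
         signif(feasible_p_range(constants)[1], 6), ")", call. = FALSE)
  }
  list(PSI_LET = PSI_LET, PSI_CET = PSI_CET, PSII = PSII,
       LHC_LET = LHC_LET, LHC_CET = LHC_CET)
}

#' Maximal linear electron transport rate from thylakoid nitrogen
#'
#' Thylakoid nitrogen assigned to the linear chain pays first for the
#' photosystems and light-harvesting complexes; the remainder buys cytochrome
#' f, whose electron capacity sets `Jmax_LET`:
#' `N_thy_LET = n_Jmax * N_ps * p / Chl`,
#' `N_LH_LET = PSII*pII_N*pII_Chl/1000 + PSI_LET*pI_N*pI_Chl/1000 +
#'  LHC_LET*l_N*l_Chl/1000`,
#' `cyt_LET = (N_thy_LET - N_LH_LET) / c_N`,
#' `Jmax_LET = max(0, cyt_LET * Chl * cyt_Jmax / 1000)`.
#'
#' @inheritParams chlorophyll_content
#' @param p proportion of linear electron transport.
#' @param Chl chlorophyll (umol m-2).
#' @param split optional precomputed [thylakoid_split()] result.
#' @return List with `Jmax_LET` (umol e- m-2 s-1), `cyt_LET` (mmol per mol
#'   Chl), `N_thy_LET`, `N_LH_LET` (umol N per umol Chl).
#' @export
jmax_let <- function(n_Jmax, N_ps, p, Chl,
                     constants = stoichiometry_constants(), split = NULL) {
  .check_scalar(n_Jmax, "n_Jmax", 0, 1)
  .check_scalar(N_ps, "N_ps", lower = 0)
  .check_scalar(p, "p", 0, 1)
  .check_scalar(Chl, "Chl", lower = 0)
  thy_n <- n_Jmax * N_ps * p
  if (Chl <= 0) {
    if (thy_n > 0) {
      stop("chlorophyll is zero but thylakoid nitrogen is positive", call. = FALSE)
    }
    return(list(Jmax_LET = 0, cyt_LET = 0, N_thy_LET = 0, N_LH_LET = 0))
  }
  split <- split %||% thylakoid_split(p, constants)
  N_thy <- thy_n / Chl
  N_LH <- split$PSII * constants$pII_N * constants$pII_Chl * 1e-3 +
    split$PSI_LET * constants$pI_N * constants$pI_Chl * 1e-3 +
    split$LHC_LET * constants$l_N * constants$l_Chl * 1e-3
  cyt <- (N_thy - N_LH) / constants$c_N
  list(Jmax_LET = max(0, cyt * Chl * constants$cyt_Jmax / 1000),
       cyt_LET = cyt, N_thy_LET = N_thy, N_LH_LET = N_LH)
}

#' Maximal cyclic electron transport rate from thylakoid nitrogen
#'
#' Analogous to [jmax_let()] for the cyclic chain (PSI and LHC only; no PSII),
#' with the additional scaling factor `Jmax_CL` relating cytochrome f to
#' `Jmax_CET` (the cyclic chain supports a higher electron capacity per
#' cytochrome f because it forgoes nitrogen-expensive PSII).
#'
#' @inheritParams jmax_let
#' @return List with `Jmax_CET`, `cyt_CET`, `N_thy_CET`, `N_LH_CET`.
#' @export
jmax_cet <- function(n_Jmax, N_ps, p, Chl,
                     constants = stoichiometry_constants(), split = NULL) {
  .check_scalar(n_Jmax, "n_Jmax", 0, 1)
  .check_scalar(N_ps, "N_ps", lower = 0)
  .check_scalar(p, "p", 0, 1)
  .check_scalar(Chl, "Chl", lower = 0)
  thy_n <- n_Jmax * N_ps * (1 - p)
  if (Chl <= 0) {
    if (thy_n > 0) {
      stop("chlorophyll is zero but thylakoid nitrogen is positive", call. = FALSE)
    }
    return(list(Jmax_CET = 0, cyt_CET = 0, N_thy_CET = 0, N_LH_CET = 0))
  }
  split <- split %||% thylakoid_split(p, constants)
  N_thy <- thy_n / Chl
  N_LH <- split$PSI_CET * constants$pI_N * constants$pI_Chl * 1e-3 +
    split$LHC_CET * constants$l_N * constants$l_Chl * 1e-3
  cyt <- (N_thy - N_LH) / constants$c_N
  list(Jmax_CET = max(0, cyt * Chl * constants$cyt_Jmax * constants$Jmax_CL / 1000),
       cyt_CET = cyt, N_thy_CET = N_thy, N_LH_CET = N_LH)
}

#' All biochemical capacities implied by a nitrogen allocation
#'
#' Composes the nitrogen-to-capacity maps into a single consistent record:
#' photosynthetic nitrogen, Rubisco sites, maximal C4-cycle activity,
#' chlorophyll, thylakoid composition and the two maximal electron transport
#' rates. All capacities are at the 25 C reference; temperature scaling is
#' applied downstream (see [apply_temperature()]).
#'
#' @param alloc an [allocation()].
#' @param env an [environment_spec()] (supplies `N_t`).
#' @param species a [species_params()] (carried through for kinetics).
#' @param constants see [stoichiometry_constants()].
#' @return An object of class `photo_capacities`.
#' @export
capacities <- function(alloc, env, species,
                       constants = stoichiometry_constants()) {
  stopifnot(inherits(alloc, "photo_allocation"), inherits(env, "photo_env"))
  N_ps <- photosynthetic_nitrogen(env$N_t, constants)
  E_tot <- rubisco_sites(alloc$n_Etot, N_ps, constants)
  V_pmax <- c4_capacity(alloc$n_C4, N_ps, constants)
  Chl <- chlorophyll_content(alloc$n_Jmax, N_ps, constants)
  if (Chl > 0) {
    split <- thylakoid_split(alloc$p, constants)
    let <- jmax_let(alloc$n_Jmax, N_ps, alloc$p, Chl, constants, split = split)
    cet <- jmax_cet(alloc$n_Jmax, N_ps, alloc$p, Chl, constants, split = split)
  } else {
    split <- list(PSI_LET = 0, PSI_CET = 0, PSII = 0, LHC_LET = 0, LHC_CET = 0)
    let <- list(Jmax_LET = 0, cyt_LET = 0, N_thy_LET = 0, N_LH_LET = 0)
    cet <- list(Jmax_CET = 0, cyt_CET = 0, N_thy_CET = 0, N_LH_CET = 0)
  }
  structure(list(
    N_ps = N_ps, E_tot = E_tot, V_pmax = V_pmax, Chl = Chl,
    Jmax_LET = let$Jmax_LET, Jmax_CET = cet$Jmax_CET,
    composition = c(split,
                    let[c("cyt_LET", "N_thy_LET", "N_LH_LET")],
                    cet[c("cyt_CET", "N_thy_CET", "N_LH_CET")])),
    class = "photo_capacities")
}

#' @export
print.photo_capacities <- function(x, ...) {
  cat("<photo_capacities>\n")
  cat("  N_ps = ", signif(x$N_ps, 5), " umol m-2, E_tot = ", signif(x$E_tot, 5),
      ", V_pmax = ", signif(x$V_pmax, 5), ", Chl = ", signif(x$Chl, 5), "\n",
      "  Jmax_LET = ", signif(x$Jmax_LET, 5), ", Jmax_CET = ",
      signif(x$Jmax_CET, 5), " umol e- m-2 s-1\n", sep = "")
  invisible(x)
}
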