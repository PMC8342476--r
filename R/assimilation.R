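# CO2 assimilation: enzyme-limited and light-limited branches.
#
# Both branches share a bundle-sheath steady state: CO2 delivered by the C4
# pump and the glycine shuttle is either fixed by bundle-sheath Rubisco,
# re-released by bundle-sheath photorespiration, or leaks back to the
# mesophyll through the bundle-sheath interface (conductance g_s). Oxygen in
# the bundle sheath is elevated in proportion to the PSII fraction p operating
# there. The steady state is found by bracketed scalar root finding on C_s
# (absolute tolerance 1e-10 ubar) with an inner fixed point for O_s.

# CO2 compensation point (ubar) from O2 (mbar) and Rubisco specificity
.gamma_star <- function(O_mbar, S_co) 0.5 * O_mbar * 1000 / S_co

# Bundle-sheath state at a trial C_s. Two carboxylation modes share the
# solver: "mm" (enzyme-limited Michaelis-Menten: a1 = beta * V_cmax,
# a2 = K_c, a3 = K_o) and "cap" (light-limited energy caps: a1 = cap for
# carboxylation, a2 = cap for oxygenation). The oxygenation ratio is
# phi = 2 Gamma* / C_s = 1000 O_s / (S_co C_s). The O2 elevation is a
# strongly contracting fixed point; `O_init` allows warm starts.
.bs_state <- function(C_s, O_m, S_co, gain, mode, a1, a2, a3, O_init = O_m) {
  O_s <- O_init
  mm <- mode == "mm"
  for (it in 1:80) {
    phi <- 1000 * O_s / (S_co * C_s)
    if (mm) {
      V_c <- a1 * C_s / (C_s + a2 * (1 + O_s / a3))
    } else {
      V_c <- if (phi <= 0) a1 else min(a1, a2 / phi)
    }
    O_new <- O_m + gain * V_c * (1 - 0.5 * phi)
    if (O_new < 0) O_new <- 0
    if (abs(O_new - O_s) < 1e-10 * (1 + O_s)) {
      O_s <- O_new
      break
    }
    O_s <- O_new
  }
  phi <- 1000 * O_s / (S_co * C_s)
  if (mm) {
    V_c <- a1 * C_s / (C_s + a2 * (1 + O_s / a3))
  } else {
    V_c <- if (phi <= 0) a1 else min(a1, a2 / phi)
  }
  V_o <- phi * V_c
  list(V_c = V_c, V_o = V_o, A_s = V_c - 0.5 * V_o, O_s = O_s)
}

# Solve the bundle-sheath CO2 balance:
#   input_flux + 0.5 * V_o_s = V_c_s + g_s * (C_s - C_m)
# input_flux = V_p + 0.5 * xi * V_o_m. Returns the steady state.
.solve_bs <- function(input_flux, g_s, C_m, O_m, S_co, p_psII, o2_diff,
                      mode, a1, a2, a3 = 1, has_bs_rubisco) {
  if (!has_bs_rubisco) {
    C_s <- C_m + input_flux / g_s
    return(list(C_s = C_s, V_c = 0, V_o = 0, A_s = 0, O_s = O_m))
  }
  gain <- p_psII / (o2_diff * g_s) / 1000
  O_warm <- O_m
  mm <- mode == "mm"
  resid <- function(C_s) {
    O_s <- O_warm
    for (it in 1:80) {
      phi <- 1000 * O_s / (S_co * C_s)
      if (mm) {
        V_c <- a1 * C_s / (C_s + a2 * (1 + O_s / a3))
      } else {
        V_c <- if (phi <= 0) a1 else min(a1, a2 / phi)
      }
      O_new <- O_m + gain * V_c * (1 - 0.5 * phi)
      if (O_new < 0) O_new <- 0
      if (abs(O_new - O_s) < 1e-10 * (1 + O_s)) {
        O_s <- O_new
        break
      }
      O_s <- O_new
    }
    O_warm <<- O_s
    phi <- 1000 * O_s / (S_co * C_s)
    if (mm) {
      V_c <- a1 * C_s / (C_s + a2 * (1 + O_s / a3))
    } else {
      V_c <- if (phi <= 0) a1 else min(a1, a2 / phi)
    }
    input_flux + 0.5 * phi * V_c - V_c - g_s * (C_s - C_m)
  }
  lo <- 1e-9
  hi <- max(C_m, 1) + input_flux / g_s + 1
  f_hi <- resid(hi)
  n_try <- 0
  while (f_hi > 0 && n_try < 80) {
    hi <- hi * 2
    f_hi <- resid(hi)
    n_try <- n_try + 1
  }
  if (f_hi > 0) {
    stop("bundle-sheath CO2 balance has no root: leakage cannot balance influx",
         call. = FALSE)
  }
  root <- stats::uniroot(resid, lower = lo, upper = hi, f.upper = f_hi,
                         tol = 1e-10, maxiter = 1000)
  st <- .bs_state(root$root, O_m, S_co, gain, mode, a1, a2, a3,
                  O_init = O_warm)
  c(list(C_s = root$root), st)
}

#' Enzyme-limited CO2 assimilation
#'
#' Rubisco- and PEPC-limited steady state for the two-compartment leaf. PEP
#' carboxylation follows Michaelis kinetics in mesophyll CO2,
#' `V_p = min(C_m V_pmax / (C_m + K_p), Vpr)`; mesophyll Rubisco (fraction
#' `1 - beta` of sites) carboxylates at the mesophyll gas levels; a fraction
#' `xi` of the glycine generated by mesophyll oxygenation is decarboxylated in
#' the bundle sheath, releasing CO2 there; bundle-sheath Rubisco (fraction
#' `beta`) operates at the elevated C_s solved from the CO2 mass balance with
#' leakage `g_s (C_s - C_m)`; bundle-sheath O2 is elevated in proportion to
#' the PSII fraction `p` operating there. Net assimilation sums both
#' compartments' carboxylation minus half their oxygenation, minus day
#' respiration.
#'
#' @param capsT temperature-adjusted capacities, see [apply_temperature()].
#' @param species a [species_params()].
#' @param env an [environment_spec()] with `C_m` resolved.
#' @param p PSII fraction operating in the bundle sheath (the LET proportion).
#' @param constants see [stoichiometry_constants()].
#' @return List with `A_c` and diagnostics `C_s`, `O_s`, `V_p`, `V_c_m`,
#'   `V_o_m`, `V_c_s`, `V_o_s`.
#' @export
enzyme_limited <- function(capsT, species, env, p,
                           constants = stoichiometry_constants()) {
  C_m <- env$C_m
  if (is.null(C_m)) stop("environment C_m not resolved; see resolve_cm()", call. = FALSE)
  if (C_m <= 0) stop("enzyme-limited model requires C_m > 0", call. = FALSE)
  O_m <- env$O
  beta <- species$beta
  g_s <- species$g_s
  S_co <- capsT$S_co
  K_eff_m <- capsT$K_c * (1 + O_m / capsT$K_o)
  V_c_m <- (1 - beta) * capsT$V_cmax * C_m / (C_m + K_eff_m)
  phi_m <- 2 * .gamma_star(O_m, S_co) / C_m
  V_o_m <- phi_m * V_c_m
  V_p <- min(C_m * capsT$V_pmax / (C_m + capsT$K_p), constants$Vpr)
  bs <- .solve_bs(V_p + 0.5 * species$xi * V_o_m, g_s, C_m, O_m, S_co,
                  p_psII = p, o2_diff = constants$o2_diff_ratio,
                  mode = "mm", a1 = beta * capsT$V_cmax, a2 = capsT$K_c,
                  a3 = capsT$K_o,
                  has_bs_rubisco = beta > 0 && capsT$V_cmax > 0)
  A_c <- V_c_m - 0.5 * V_o_m + bs$V_c - 0.5 * bs$V_o - constants$R_d
  list(A_c = A_c, C_s = bs$C_s, O_s = bs$O_s, V_p = V_p,
       V_c_m = V_c_m, V_o_m = V_o_m, V_c_s = bs$V_c, V_o_s = bs$V_o)
}

# one light-limited branch (currency = "ATP" or "NADPH")
.light_branch <- function(currency, supply, atp_rate, partition, capsT,
                          species, env, constants) {
  C_m <- env$C_m
  O_m <- env$O
  S_co <- capsT$S_co
  cost_cb <- if (currency == "ATP") 3 else 2
  cost_pr <- if (currency == "ATP") 3.5 else 2
  # the C4 pump is ATP-driven in both branches (2 ATP per PEP regenerated)
  V_p <- min(partition$f_c4 * atp_rate / 2,
             C_m * capsT$V_pmax / (C_m + capsT$K_p), constants$Vpr)
  phi_m <- 2 * .gamma_star(O_m, S_co) / C_m
  cap_cb_m <- partition$f_cb_m * supply / cost_cb
  cap_pr_m <- partition$f_pr_m * supply / cost_pr
  V_c_m <- if (phi_m <= 0) cap_cb_m else min(cap_cb_m, cap_pr_m / phi_m)
  V_o_m <- phi_m * V_c_m
  cap_cb_s <- partition$f_cb_s * supply / cost_cb
  cap_pr_s <- partition$f_pr_s * supply / cost_pr
  bs <- .solve_bs(V_p + 0.5 * species$xi * V_o_m, species$g_s, C_m, O_m, S_co,
                  p_psII = partition$p_psII %||% 0,
                  o2_diff = constants$o2_diff_ratio,
                  mode = "cap", a1 = cap_cb_s, a2 = cap_pr_s,
                  has_bs_rubisco = cap_cb_s > 0)
  A <- V_c_m - 0.5 * V_o_m + bs$V_c - 0.5 * bs$V_o - constants$R_d
  list(A = A, C_s = bs$C_s, O_s = bs$O_s, V_p = V_p,
       V_c_m = V_c_m, V_o_m = V_o_m, V_c_s = bs$V_c, V_o_s = bs$V_o)
}

#' Light-limited CO2 assimilation
#'
#' ATP- and NADPH-limited assimilation given the energy partition. Each
#' consuming pool receives its fraction of the ATP and NADPH supplies; demand
#' stoichiometry is 3 ATP + 2 NADPH per carboxylation, 3.5 ATP + 2 NADPH per
#' oxygenation, and 2 ATP per PEP regenerated by the C4 cycle (no NADPH).
#' Within each compartment, oxygenation is stoichiometrically coupled to
#' carboxylation through the oxygenation ratio `phi = 2 Gamma* / C`, so
#' carboxylation runs at the lower of its own energy cap and the
#' photorespiratory pool's cap divided by `phi`. The bundle-sheath CO2 level
#' is solved self-consistently with leakage in each branch. The light-limited
#' rate is the minimum of the two currency-limited rates.
#'
#' @param capsT temperature-adjusted capacities, see [apply_temperature()].
#' @param fluxes list with `atp_rate` and `nadph_rate` (from [energy_supply()]).
#' @param partition an [energy_partition()].
#' @param species a [species_params()].
#' @param env an [environment_spec()] with `C_m` resolved.
#' @param p_psII PSII fraction operating in the bundle sheath (the LET
#'   proportion of the allocation).
#' @param constants see [stoichiometry_constants()].
#' @return List with `A_j_ATP`, `A_j_NADPH`, `A_j` and per-branch diagnostics.
#' @export
light_limited <- function(capsT, fluxes, partition, species, env, p_psII = 0,
                          constants = stoichiometry_constants()) {
  if (is.null(env$C_m)) stop("environment C_m not resolved; see resolve_cm()", call. = FALSE)
  if (env$C_m <= 0) stop("light-limited model requires C_m > 0", call. = FALSE)
  part <- unclass(partition)
  part$p_psII <- p_psII
  atp <- .light_branch("ATP", fluxes$atp_rate, fluxes$atp_rate, part, capsT,
                       species, env, constants)
  nad <- .light_branch("NADPH", fluxes$nadph_rate, fluxes$atp_rate, part,
                       capsT, species, env, constants)
  list(A_j_ATP = atp$A, A_j_NADPH = nad$A, A_j = min(atp$A, nad$A),
       atp_branch = atp, nadph_branch = nad)
}

#' Combine the light- and enzyme-limited rates
#'
#' The realized assimilation is the lower of the light-limited and
#' enzyme-limited rates; ties are labeled `"enzyme"` (fixed for
#' reproducibility). Within the light-limited rate, the limiting currency is
#' reported (`"ATP"` on an inner tie).
#'
#' @param light result of [light_limited()] (or a list with `A_j_ATP`,
#'   `A_j_NADPH`, `A_j`).
#' @param enzyme result of [enzyme_limited()] (or a list with `A_c`).
#' @return An object of class `photo_assim` with fields `A`, `A_j_ATP`,
#'   `A_j_NADPH`, `A_j`, `A_c`, `limiting` and `diagnostics`.
#' @export
net_assimilation <- function(light, enzyme) {
  A_j <- light$A_j
  A_c <- enzyme$A_c
  stopifnot(is.finite(A_j), is.finite(A_c))
  if (A_c <= A_j) {
    A <- A_c
    limiting <- "enzyme"
  } else {
    A <- A_j
    limiting <- if (light$A_j_ATP <= light$A_j_NADPH) "ATP" else "NADPH"
  }
  structure(list(A = A, A_j_ATP = light$A_j_ATP, A_j_NADPH = light$A_j_NADPH,
                 A_j = A_j, A_c = A_c, limiting = limiting,
                 diagnostics = list(enzyme = enzyme,
                                    atp_branch = light$atp_branch,
                                    nadph_branch = light$nadph_branch)),
            class = "photo_assim")
}

#' @export
print.photo_assim <- function(x, ...) {
  cat("<photo_assim> A = ", signif(x$A, 6), " umol m-2 s-1 (", x$limiting,
      "-limited)\n  A_j_ATP = ", signif(x$A_j_ATP, 6), ", A_j_NADPH = ",
      signif(x$A_j_NADPH, 6), ", A_c = ", signif(x$A_c, 6), "\n", sep = "")
  invisible(x)
}

#' Full forward simulation of CO2 assimilation
#'
#' Deterministic composition of the model stages: nitrogen allocation to
#' capacities, temperature scaling, light absorption and electron transport,
#' ATP/NADPH supply, and the light- and enzyme-limited assimilation rates,
#' returning their minimum. This is the objective evaluated by the optimizer.
#'
#' @param species a [species_params()].
#' @param env an [environment_spec()]; `C_m` is resolved against the species
#'   if only `C_a` is given.
#' @param alloc an [allocation()].
#' @param partition an [energy_partition()].
#' @param constants see [stoichiometry_constants()].
#' @param tparams see [temperature_params()].
#' @return An object of class `photo_assim` (see [net_assimilation()]), with
#'   additional diagnostics `fluxes` (electron transport and energy supply)
#'   and `capacities`.
#' @examples
#' sp <- species_archetypes()[["C3"]]
#' env <- environment_spec(I = 1000, T_leaf = 25, N_t = 130, C_m = 250)
#' al <- allocation(0.55, 0, 0.45, p = 0.95)
#' pt <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
#' simulate_assimilation(sp, env, al, pt)
#' @export
simulate_assimilation <- function(species, env, alloc, partition,
                                  constants = stoichiometry_constants(),
                                  tparams = temperature_params()) {
  stopifnot(inherits(species, "photo_species"), inherits(alloc, "photo_allocation"),
            inherits(partition, "photo_partition"))
  env <- resolve_cm(env, species)
  caps <- capacities(alloc, env, species, constants)
  capsT <- apply_temperature(caps, species, env, tparams)
  ab <- absorbed_irradiance(env$I, alloc$p, constants)
  J_LET <- electron_transport(ab$I_LET, capsT$Jmax_LET, constants$Theta)
  J_CET <- electron_transport(ab$I_CET, capsT$Jmax_CET, constants$Theta)
  supply <- energy_supply(J_LET, J_CET, constants)
  fluxes <- list(I_LET = ab$I_LET, I_CET = ab$I_CET, J_LET = J_LET,
                 J_CET = J_CET, J_t = J_LET + J_CET,
                 atp_rate = supply$atp_rate, nadph_rate = supply$nadph_rate)
  lj <- light_limited(capsT, fluxes, partition, species, env,
                      p_psII = alloc$p, constants = constants)
  ej <- enzyme_limited(capsT, species, env, alloc$p, constants)
  out <- net_assimilation(lj, ej)
  out$fluxes <- fluxes
  out$capacities <- caps
  out$capacities_T <- capsT
  out$env <- env
  out$alloc <- alloc
  out$partition <- partition
  out
}
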