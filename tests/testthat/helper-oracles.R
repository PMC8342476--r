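# Independent straight-line oracles, written as literal transcriptions of the
# model equations with hard-coded reference constants. They deliberately do
# not call any package function so that agreement is a genuine cross-check.

# Nitrogen-to-capacity chain (reference constants inlined)
oracle_capacities <- function(n_Etot, n_C4, n_Jmax, p, N_ps) {
  E_tot <- n_Etot * N_ps * 1.27e-3
  mw_star_ppdk <- 0.16 * 95000 / 14
  mw_star_pepc <- 0.16 * 96000 / 14
  V_pmax <- n_C4 * N_ps / (mw_star_ppdk / 6.02 + mw_star_pepc / 66)
  Chl <- 0.0158887 * n_Jmax * N_ps
  PSI_LET <- 2 * p
  PSI_CET <- 2 * (1 - p)
  PSII <- 2.5
  LHC_LET <- (1000 * p - PSII * 60 - PSI_LET * 184) / 13
  LHC_CET <- (1000 * (1 - p) - PSI_CET * 184) / 13
  N_thy_LET <- n_Jmax * N_ps * p / Chl
  N_LH_LET <- PSII * 83.3 * 60 * 1e-3 + PSI_LET * 32.8 * 184 * 1e-3 +
    LHC_LET * 26 * 13 * 1e-3
  cyt_LET <- (N_thy_LET - N_LH_LET) / 8.85
  Jmax_LET <- max(0, cyt_LET * Chl * 172 / 1000)
  N_thy_CET <- n_Jmax * N_ps * (1 - p) / Chl
  N_LH_CET <- PSI_CET * 32.8 * 184 * 1e-3 + LHC_CET * 26 * 13 * 1e-3
  cyt_CET <- (N_thy_CET - N_LH_CET) / 8.85
  Jmax_CET <- max(0, cyt_CET * Chl * 172 * 3 / 1000)
  list(E_tot = E_tot, V_pmax = V_pmax, Chl = Chl,
       PSI_LET = PSI_LET, PSI_CET = PSI_CET, PSII = PSII,
       LHC_LET = LHC_LET, LHC_CET = LHC_CET,
       N_thy_LET = N_thy_LET, N_LH_LET = N_LH_LET, cyt_LET = cyt_LET,
       Jmax_LET = Jmax_LET,
       N_thy_CET = N_thy_CET, N_LH_CET = N_LH_CET, cyt_CET = cyt_CET,
       Jmax_CET = Jmax_CET)
}

# Non-rectangular hyperbola, quadratic formula
oracle_hyperbola <- function(I_abso, Jmax, Theta = 0.7) {
  if (I_abso == 0 || Jmax == 0) return(0)
  (I_abso + Jmax - sqrt((I_abso + Jmax)^2 - 4 * Theta * I_abso * Jmax)) /
    (2 * Theta)
}

# Single-compartment Farquhar-type C3 model: enzyme-limited rate and
# light-limited rate for a single mesophyll Calvin-Benson + photorespiration
# energy split. Gamma* = 0.5 * O * 1000 / S_co (O mbar -> ubar).
oracle_c3 <- function(Vcmax, K_c, K_o, S_co, C_m, O, I, Jmax_LET, Jmax_CET,
                      f_cb, f_pr, p, Theta = 0.7, alpha = 0.84, f = 0.15,
                      e_ATP = 4 / 3, h_per_atp = 4) {
  gstar <- 0.5 * O * 1000 / S_co
  phi <- 2 * gstar / C_m
  A_c <- Vcmax * C_m / (C_m + K_c * (1 + O / K_o)) * (1 - gstar / C_m)
  I_LET <- I * alpha * (1 - f) * p * 0.5
  I_CET <- I * alpha * (1 - f) * (1 - p)
  J_LET <- oracle_hyperbola(I_LET, Jmax_LET, Theta)
  J_CET <- oracle_hyperbola(I_CET, Jmax_CET, Theta)
  atp <- J_LET / e_ATP + J_CET * 2 / h_per_atp
  nadph <- J_LET / 2
  vc_atp <- if (phi > 0) min(f_cb * atp / 3, f_pr * atp / (3.5 * phi)) else f_cb * atp / 3
  vc_nad <- if (phi > 0) min(f_cb * nadph / 2, f_pr * nadph / (2 * phi)) else f_cb * nadph / 2
  A_j_ATP <- vc_atp * (1 - 0.5 * phi)
  A_j_NADPH <- vc_nad * (1 - 0.5 * phi)
  list(A_c = A_c, A_j_ATP = A_j_ATP, A_j_NADPH = A_j_NADPH,
       A_j = min(A_j_ATP, A_j_NADPH),
       A = min(A_c, min(A_j_ATP, A_j_NADPH)))
}

# convenience fixtures
c3_archetype <- function() species_archetypes()[["C3"]]
c4_archetype <- function() species_archetypes()[["C4"]]

test_env <- function(I = 1000, T_leaf = 25, N_t = 130, C_m = 250, O = 210,
                     ...) {
  environment_spec(I = I, T_leaf = T_leaf, N_t = N_t, C_m = C_m, O = O, ...)
}
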