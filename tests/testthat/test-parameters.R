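# Constants, environments, species definitions and unit conversions.

test_that("every reference constant matches its printed value exactly", {
  # literal table, asserted against the shipped defaults one by one
  expected <- c(
    c_E = 1.27e-3, c_N = 8.85, cyt_Jmax = 172, e_ATP = 4 / 3, f = 0.15,
    alpha = 0.84, Theta = 0.7, Jmax_CL = 3, n_Chl = 0.0158887, PSI = 2,
    PSII = 2.5, pI_Chl = 184, pII_Chl = 60, l_Chl = 13, pI_N = 32.8,
    pII_N = 83.3, l_N = 26, MW_PEPC = 96000, MW_PPDK = 95000,
    kcat_PEPC = 66, kcat_PPDK = 6.02, protein_N_fraction = 0.16)
  cs <- stoichiometry_constants()
  for (nm in names(expected)) {
    expect_identical(cs[[nm]], unname(expected[nm]), label = nm)
  }
  # each appears exactly once among the defaults
  expect_true(all(names(expected) %in% names(cs)))
  expect_false(any(duplicated(names(cs))))
})

test_that("constant overrides are applied and provenance is recorded", {
  cs <- stoichiometry_constants(Theta = 0.9)
  expect_equal(cs$Theta, 0.9)
  expect_equal(cs$alpha, 0.84)
  prov <- attr(cs, "provenance")
  expect_equal(unname(prov["Theta"]), "user")
  expect_equal(unname(prov["alpha"]), "default")
  expect_error(stoichiometry_constants(bogus = 1), "unknown constant")
  expect_error(stoichiometry_constants(alpha = -0.5), "positive")
})

test_that("mesophyll CO2 derivation follows the diffusion ratios", {
  expect_equal(derive_cm(380, 1.0, 1.0), 380)
  expect_equal(derive_cm(280, 2.0, 0.85), 119)
  expect_error(derive_cm(380, 0.9, 0.85), "Ca_over_Ci")
  expect_error(derive_cm(380, 1.5, 1.2), "diffusion")
})

test_that("in vitro PEPC activity is divided by three", {
  expect_equal(pepc_invitro_to_invivo(0), 0)
  expect_equal(pepc_invitro_to_invivo(300), 100)
  expect_equal(pepc_invitro_to_invivo(66), 22)
  expect_error(pepc_invitro_to_invivo(-1), "non-negative")
})

test_that("species validation enforces the C3 ban on C4-cycle investment", {
  expect_error(
    species_params("bad", "C3", beta = 0, k_ccat = 3.5, xi = 0, K_p = 80,
                   g_s = 0.003, allocation_bounds = list(n_C4 = c(0, 0.2))),
    "C3 species")
  ok <- species_params("ok", "C3", beta = 0, k_ccat = 3.5, xi = 0, K_p = 80,
                       g_s = 0.003)
  expect_identical(ok$allocation_bounds$n_C4, c(0, 0))
  expect_error(
    species_params("bad", "C4", beta = 1.2, k_ccat = 5, xi = 1, K_p = 80,
                   g_s = 0.003),
    "beta")
})

test_that("the Rubisco trade-off reproduces its anchor and is monotone", {
  kin <- rubisco_kinetics(3.5)
  expect_equal(kin$K_c25, 650)
  expect_equal(kin$K_o25, 450)
  expect_equal(kin$S_co25, 2590)
  fast <- rubisco_kinetics(5.44)
  expect_gt(fast$K_c25, kin$K_c25)
  expect_lt(fast$S_co25, kin$S_co25)
})

test_that("environment presets cover the study conditions", {
  pre <- environment_presets()
  expect_named(pre, c("evolutionary", "growth_aci", "growth_nitrogen",
                      "growth_alloc_25", "growth_alloc_35"))
  expect_equal(pre$evolutionary$C_a, 280)
  expect_equal(pre$evolutionary$O, 200)
  expect_equal(pre$growth_aci$I, 560)
  expect_equal(pre$growth_aci$T_leaf, 37)
  expect_equal(pre$growth_nitrogen$I, 554)
  expect_equal(pre$growth_nitrogen$T_leaf, 30)
  expect_equal(pre$growth_alloc_25$T_leaf, 25)
  expect_equal(pre$growth_alloc_35$T_leaf, 35)
  expect_equal(pre$growth_alloc_25$C_a, 380)
})

test_that("C_m resolution uses species-specific drawdown ratios", {
  env <- environment_spec(I = 1000, T_leaf = 25, N_t = 130, C_a = 380)
  c3 <- resolve_cm(env, c3_archetype())
  c4 <- resolve_cm(env, c4_archetype())
  expect_equal(c3$C_m, 380 * 0.7 * 0.85)
  expect_equal(c4$C_m, 380 * 0.4 * 0.85)
  expect_lt(c4$C_m, c3$C_m)
  # explicit C_m wins
  env2 <- environment_spec(I = 1000, T_leaf = 25, N_t = 130, C_m = 123)
  expect_equal(resolve_cm(env2, c3_archetype())$C_m, 123)
})

test_that("environment validation rejects impossible gas settings", {
  expect_error(environment_spec(I = -1, T_leaf = 25, N_t = 130, C_m = 100), "I")
  expect_error(environment_spec(I = 1, T_leaf = 25, N_t = 130), "C_m or C_a")
  expect_error(environment_spec(I = 1, T_leaf = 25, N_t = 130, C_m = 400,
                                C_a = 380), "diffusion")
})
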