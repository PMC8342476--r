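# Light- and enzyme-limited assimilation and their composition.

test_that("the C3 stoichiometric limits hold with all energy to the mesophyll", {
  # phi = 0 via O = 0: A_j_NADPH = J_LET / 4, A_j_ATP = atp / 3
  sp <- c3_archetype()
  env <- test_env(I = 800, T_leaf = 25, C_m = 250, O = 0)
  alloc <- allocation(0.5, 0, 0.5, p = 1)
  part <- energy_partition(f_cb_m = 1)
  res <- simulate_assimilation(sp, env, alloc, part)
  J_LET <- res$fluxes$J_LET
  expect_gt(J_LET, 0)
  expect_equal(res$A_j_NADPH, J_LET / 4, tolerance = 1e-12)
  expect_equal(res$A_j_ATP, res$fluxes$atp_rate / 3, tolerance = 1e-12)
})

test_that("zero light and zero nitrogen both give zero assimilation", {
  sp <- c3_archetype()
  alloc <- allocation(0.5, 0, 0.5, p = 0.95)
  part <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
  dark <- simulate_assimilation(sp, test_env(I = 0), alloc, part)
  expect_equal(dark$A_j, 0)
  expect_equal(dark$A, 0)
  starved <- simulate_assimilation(sp, test_env(N_t = 0), alloc, part)
  expect_equal(starved$A, 0)
})

test_that("A_j is non-decreasing along a 20-point light ramp", {
  sp <- c4_archetype()
  alloc <- allocation(0.35, 0.1, 0.55, p = 0.7)
  part <- energy_partition(0.25, 0.05, 0.35, 0.05, 0.3)
  A_j <- vapply(seq(50, 2000, length.out = 20), function(I) {
    simulate_assimilation(sp, test_env(I = I, C_m = 100, O = 200), alloc,
                          part)$A_j
  }, numeric(1))
  expect_true(all(diff(A_j) >= -1e-9))
})

test_that("the full model collapses to the Farquhar C3 oracle", {
  # V_pmax = 0 (no C4 pool), xi = 0, beta = 0: single-compartment C3 plant
  sp <- c3_archetype()
  alloc <- allocation(0.5, 0, 0.5, p = 0.95)
  part <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
  env0 <- test_env()
  caps <- capacities(alloc, env0, sp)
  for (C_m in c(50, 120, 250, 400, 800)) {
    for (I in c(100, 300, 700, 1200, 2000)) {
      env <- test_env(I = I, C_m = C_m)
      res <- simulate_assimilation(sp, env, alloc, part)
      orc <- oracle_c3(Vcmax = caps$E_tot * sp$k_ccat, K_c = sp$K_c25,
                       K_o = sp$K_o25, S_co = sp$S_co25, C_m = C_m, O = env$O,
                       I = I, Jmax_LET = caps$Jmax_LET,
                       Jmax_CET = caps$Jmax_CET, f_cb = 0.8, f_pr = 0.2,
                       p = 0.95)
      expect_equal(res$A_c, orc$A_c, tolerance = 1e-10)
      expect_equal(res$A_j_ATP, orc$A_j_ATP, tolerance = 1e-10)
      expect_equal(res$A_j_NADPH, orc$A_j_NADPH, tolerance = 1e-10)
      expect_equal(res$A, orc$A, tolerance = 1e-10)
    }
  }
})

test_that("enzyme-limited rate saturates in C_m and grows with Rubisco", {
  sp <- c3_archetype()
  part <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
  alloc <- allocation(0.5, 0, 0.5, p = 0.95)
  sat <- simulate_assimilation(sp, test_env(C_m = 1e6, I = 1000), alloc, part)
  caps <- capacities(alloc, test_env(), sp)
  expect_equal(sat$A_c, caps$E_tot * sp$k_ccat, tolerance = 1e-3)
  # A_c strictly increasing in E_tot (via n_Etot) at fixed environment
  A_c <- vapply(seq(0.05, 0.95, length.out = 10), function(nE) {
    al <- allocation(nE, 0, 1 - nE, p = 0.95)
    simulate_assimilation(sp, test_env(), al, part)$A_c
  }, numeric(1))
  expect_true(all(diff(A_c) > 0))
})

test_that("raising C_m never decreases A for a C3 allocation", {
  sp <- c3_archetype()
  alloc <- allocation(0.55, 0, 0.45, p = 0.95)
  part <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
  A <- vapply(seq(50, 150, length.out = 8), function(C_m) {
    simulate_assimilation(sp, test_env(C_m = C_m), alloc, part)$A
  }, numeric(1))
  expect_true(all(diff(A) >= -1e-9))
})

test_that("the minimum structure and tie rule are respected", {
  l <- list(A_j_ATP = 10, A_j_NADPH = 12, A_j = 10)
  r <- net_assimilation(l, list(A_c = 8))
  expect_equal(r$A, 8)
  expect_equal(r$limiting, "enzyme")
  r2 <- net_assimilation(l, list(A_c = 11))
  expect_equal(r2$A, 10)
  expect_equal(r2$limiting, "ATP")
  r3 <- net_assimilation(list(A_j_ATP = 12, A_j_NADPH = 10, A_j = 10),
                         list(A_c = 11))
  expect_equal(r3$limiting, "NADPH")
  rtie <- net_assimilation(l, list(A_c = 10))
  expect_equal(rtie$A, 10)
  expect_equal(rtie$limiting, "enzyme")
  # A <= both branches; perturbing the slack branch leaves A unchanged
  sp <- c4_archetype()
  alloc <- allocation(0.35, 0.1, 0.55, p = 0.7)
  part <- energy_partition(0.25, 0.05, 0.35, 0.05, 0.3)
  res <- simulate_assimilation(sp, test_env(I = 1500, C_m = 100, O = 200),
                               alloc, part)
  expect_lte(res$A, res$A_j + 1e-12)
  expect_lte(res$A, res$A_c + 1e-12)
})

test_that("bundle-sheath CO2 is conserved at the solved steady state", {
  sp <- c4_archetype()
  alloc <- allocation(0.35, 0.1, 0.55, p = 0.7)
  env <- test_env(I = 1500, C_m = 100, O = 200, T_leaf = 30)
  part <- energy_partition(0.25, 0.05, 0.35, 0.05, 0.3)
  res <- simulate_assimilation(sp, env, alloc, part)
  ej <- res$diagnostics$enzyme
  residual <- ej$V_p + 0.5 * sp$xi * ej$V_o_m + 0.5 * ej$V_o_s - ej$V_c_s -
    sp$g_s * (ej$C_s - env$C_m)
  expect_lt(abs(residual), 1e-9)
  # bundle-sheath CO2 and O2 are elevated above mesophyll levels
  expect_gt(ej$C_s, env$C_m)
  expect_gt(ej$O_s, env$O)
})

test_that("the glycine shuttle feeds bundle-sheath refixation", {
  # with xi = 1 mesophyll photorespiratory CO2 surfaces in the bundle sheath,
  # where elevated C_s lets Rubisco refix it: A_c must not fall below xi = 0
  sp1 <- species_params("shuttle", "C3-C4", beta = 0.5, k_ccat = 3.8, xi = 1,
                        K_p = 80, g_s = 0.003)
  sp0 <- species_params("noshuttle", "C3-C4", beta = 0.5, k_ccat = 3.8, xi = 0,
                        K_p = 80, g_s = 0.003)
  alloc <- allocation(0.55, 0, 0.45, p = 0.8)
  part <- energy_partition(0.3, 0.1, 0.5, 0.1, 0)
  env <- test_env(I = 1200, C_m = 80)
  A1 <- simulate_assimilation(sp1, env, alloc, part)$A_c
  A0 <- simulate_assimilation(sp0, env, alloc, part)$A_c
  expect_gt(A1, A0)
})
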