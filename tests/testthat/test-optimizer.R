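# Allocation optimizer. Unit tests run with reduced budgets; the full
# optimizer-vs-oracle comparison lives in the acceptance suite.

cheap <- optimizer_settings(n_starts = 6, maxit = 600)

test_that("a C3 species never invests in the C4 cycle and hits zero exactly", {
  opt <- optimize_allocation(c3_archetype(),
                             test_env(I = 800, C_m = 200), cheap)
  expect_identical(opt$alloc$n_C4, 0)
  expect_identical(opt$partition$f_c4, 0)
  expect_gt(opt$A_star, 0)
  expect_lt(opt$constraint_violation, 1e-6)
})

test_that("zero leaf nitrogen is a degenerate optimum with A* = 0", {
  opt <- optimize_allocation(c4_archetype(), test_env(N_t = 0), cheap)
  expect_equal(opt$A_star, 0)
  expect_true(opt$converged)
})

test_that("identical settings give bitwise-identical results", {
  s <- optimizer_settings(n_starts = 4, maxit = 300, seed = 7)
  env <- test_env(I = 900, C_m = 120, O = 200)
  o1 <- optimize_allocation(c4_archetype(), env, s)
  o2 <- optimize_allocation(c4_archetype(), env, s)
  expect_identical(unclass(o1$alloc), unclass(o2$alloc))
  expect_identical(o1$A_star, o2$A_star)
})

test_that("A* is re-verified by a fresh simulation of the optimum", {
  env <- test_env(I = 900, C_m = 120, O = 200)
  opt <- optimize_allocation(c4_archetype(), env, cheap)
  redo <- simulate_assimilation(c4_archetype(), env, opt$alloc, opt$partition)
  expect_equal(opt$A_star, redo$A, tolerance = 1e-8)
})

test_that("the optimizer matches a coarse grid oracle on a C3 case", {
  env <- test_env(I = 700, C_m = 180)
  opt <- optimize_allocation(c3_archetype(), env,
                             optimizer_settings(n_starts = 10, maxit = 1000))
  orc <- grid_oracle(c3_archetype(), env, resolution = 9)
  expect_lt(abs(opt$A_star - orc$A_star) / orc$A_star, 1e-3)
  # dominance: the continuous optimizer is not beaten by the raw grid
  expect_gte(opt$A_star, orc$A_star_grid - 1e-6 * orc$A_star_grid)
})

test_that("grid refinement never lowers the oracle value", {
  env <- test_env(I = 700, C_m = 180)
  o5 <- grid_oracle(c3_archetype(), env, resolution = 5, polish = FALSE)
  o9 <- grid_oracle(c3_archetype(), env, resolution = 9, polish = FALSE)
  expect_gte(o9$A_star_grid, o5$A_star_grid - 1e-9)
  expect_gte(o9$A_star, o9$A_star_grid - 1e-9)
})

test_that("A* is monotone in leaf nitrogen and in irradiance", {
  a <- vapply(c(60, 130, 220), function(N) {
    optimize_allocation(c3_archetype(), test_env(N_t = N), cheap)$A_star
  }, numeric(1))
  expect_true(all(diff(a) > -1e-6))
  b <- vapply(c(300, 800, 1600), function(I) {
    optimize_allocation(c3_archetype(), test_env(I = I), cheap)$A_star
  }, numeric(1))
  expect_true(all(diff(b) > -1e-6))
})

test_that("re-optimizing energy in the same environment is a fixed point", {
  env <- test_env(I = 900, C_m = 120, O = 200)
  opt <- optimize_allocation(c4_archetype(), env,
                             optimizer_settings(n_starts = 10, maxit = 1500))
  re <- optimize_energy_given_nitrogen(opt$alloc, c4_archetype(), env)
  expect_equal(re$A_star, opt$A_star, tolerance = 1e-4)
  expect_gte(re$A_star, opt$A_star - 1e-6)
  # nitrogen pools are untouched
  expect_identical(re$alloc$n_Etot, opt$alloc$n_Etot)
  expect_identical(re$alloc$n_C4, opt$alloc$n_C4)
})

test_that("energy re-optimization in a new environment dominates a frozen partition", {
  env_g <- test_env(I = 554, T_leaf = 30, C_m = 120, O = 210)
  env_m <- test_env(I = 1500, T_leaf = 35, C_m = 120, O = 210)
  opt_g <- optimize_allocation(c4_archetype(), env_g, cheap)
  frozen <- simulate_assimilation(c4_archetype(), env_m, opt_g$alloc,
                                  opt_g$partition)
  re <- optimize_energy_given_nitrogen(opt_g$alloc, c4_archetype(), env_m)
  expect_gte(re$A_star, frozen$A - 1e-8)
  # C3 allocation: no C4 energy demand
  opt_c3 <- optimize_allocation(c3_archetype(), env_g, cheap)
  re_c3 <- optimize_energy_given_nitrogen(opt_c3$alloc, c3_archetype(), env_m)
  expect_identical(re_c3$partition$f_c4, 0)
})

test_that("the optimum shows co-limitation of the assimilation branches", {
  # at an interior optimum the binding branches cannot differ much: nitrogen
  # or energy could otherwise be shifted profitably
  env <- environment_spec(I = 1500, T_leaf = 30, N_t = 130, C_a = 280, O = 200)
  opt <- optimize_allocation(c4_archetype(), env,
                             optimizer_settings(n_starts = 12, maxit = 2000))
  r <- opt$result
  expect_lt(abs(r$A_j_ATP - r$A_j_NADPH) / r$A, 0.01)
  expect_lt(abs(r$A_j - r$A_c) / r$A, 0.01)
})
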