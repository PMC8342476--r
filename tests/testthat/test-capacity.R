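# Nitrogen-to-capacity stoichiometry.

test_that("Rubisco sites, C4 capacity and chlorophyll scale as products", {
  expect_equal(rubisco_sites(0, 5e4), 0)
  expect_equal(rubisco_sites(1, 1000), 1.27)
  expect_equal(rubisco_sites(0.4, 1e5), 50.8)
  expect_equal(c4_capacity(0, 1e5), 0)
  expect_equal(c4_capacity(0.05, 1e5), 25.384, tolerance = 1e-4)
  expect_equal(c4_capacity(0.1, 1e5), 2 * c4_capacity(0.05, 1e5))
  expect_equal(chlorophyll_content(0, 1e5), 0)
  expect_equal(chlorophyll_content(0.25, 1e5), 397.2175)
  expect_equal(chlorophyll_content(0.5, 2e5), 4 * chlorophyll_content(0.25, 1e5))
})

test_that("photosynthetic nitrogen map is monotone with phi(0) = 0", {
  expect_equal(photosynthetic_nitrogen(0), 0)
  expect_equal(photosynthetic_nitrogen(100), 75000)
  expect_gte(photosynthetic_nitrogen(130), photosynthetic_nitrogen(50))
  expect_error(photosynthetic_nitrogen(-1), "non-negative")
  # custom map hook
  expect_equal(photosynthetic_nitrogen(10, fun = function(n) 500 * n), 5000)
})

test_that("thylakoid split obeys the chlorophyll bookkeeping", {
  cs <- stoichiometry_constants()
  s1 <- thylakoid_split(1)
  expect_equal(s1$PSI_LET, 2)
  expect_equal(s1$PSI_CET, 0)
  expect_equal(s1$LHC_LET, (1000 - 150 - 368) / 13)
  expect_equal(s1$LHC_CET, 0)
  # p below the feasibility threshold: photosystems exceed the LET share
  expect_error(thylakoid_split(0), "infeasible")
  expect_error(thylakoid_split(0.1), "infeasible")
  # bookkeeping: chlorophyll in the LET share is fully accounted for
  for (p in c(0.3, 0.6, 0.95, 1)) {
    s <- thylakoid_split(p)
    expect_equal(s$PSII * cs$pII_Chl + s$PSI_LET * cs$pI_Chl +
                   s$LHC_LET * cs$l_Chl, 1000 * p, tolerance = 1e-9)
    expect_equal(s$PSI_CET * cs$pI_Chl + s$LHC_CET * cs$l_Chl,
                 1000 * (1 - p), tolerance = 1e-9)
  }
})

test_that("the worked LET/CET chain reproduces the hand evaluation", {
  Chl <- chlorophyll_content(0.25, 1e5)
  let <- jmax_let(0.25, 1e5, 0.95, Chl)
  expect_equal(let$N_thy_LET, 59.79, tolerance = 1e-3)
  expect_equal(let$N_LH_LET, 35.67, tolerance = 1e-3)
  expect_equal(let$cyt_LET, 2.725, tolerance = 1e-3)
  expect_equal(let$Jmax_LET, 186.2, tolerance = 1e-3)
  cet <- jmax_cet(0.25, 1e5, 0.95, Chl)
  expect_equal(cet$N_thy_CET, 3.147, tolerance = 1e-3)
  expect_equal(cet$N_LH_CET, 1.425, tolerance = 1e-3)
  expect_equal(cet$cyt_CET, 0.1946, tolerance = 1e-3)
  expect_equal(cet$Jmax_CET, 39.9, tolerance = 1e-2)
})

test_that("Jmax values clamp at zero when light harvesting outcosts thylakoid N", {
  # thylakoid nitrogen spread over a large chlorophyll pool: N_thy < N_LH,
  # cytochrome f would be negative, so Jmax clamps to zero
  let <- jmax_let(0.02, 1e5, 0.95, Chl = 5000)
  expect_lt(let$N_thy_LET - let$N_LH_LET, 0)
  expect_lt(let$cyt_LET, 0)
  expect_equal(let$Jmax_LET, 0)
  cet <- jmax_cet(0.25, 1e5, 1, Chl = chlorophyll_content(0.25, 1e5))
  expect_equal(cet$Jmax_CET, 0)  # p = 1: no CET nitrogen
  # with the shipped chlorophyll relation, thylakoid N per chlorophyll is
  # p / n_Chl by construction, so the LET chain is never clamped for valid p
  expect_gt(jmax_let(0.5, 1e5, 0.95,
                     chlorophyll_content(0.5, 1e5))$Jmax_LET, 0)
})

test_that("capacities() agrees componentwise with an independent transcription", {
  set.seed(42)
  sp <- c4_archetype()
  for (i in 1:20) {
    w <- stats::runif(3)
    w <- w / sum(w)
    p <- stats::runif(1, 0.3, 1)
    N_t <- stats::runif(1, 20, 300)
    alloc <- allocation(w[1], w[2], w[3], p)
    env <- test_env(N_t = N_t)
    caps <- capacities(alloc, env, sp)
    orc <- oracle_capacities(w[1], w[2], w[3], p, caps$N_ps)
    expect_equal(caps$E_tot, orc$E_tot, tolerance = 1e-12)
    expect_equal(caps$V_pmax, orc$V_pmax, tolerance = 1e-12)
    expect_equal(caps$Chl, orc$Chl, tolerance = 1e-12)
    expect_equal(caps$Jmax_LET, orc$Jmax_LET, tolerance = 1e-12)
    expect_equal(caps$Jmax_CET, orc$Jmax_CET, tolerance = 1e-12)
    expect_equal(caps$composition$cyt_LET, orc$cyt_LET, tolerance = 1e-12)
    expect_equal(caps$composition$cyt_CET, orc$cyt_CET, tolerance = 1e-12)
  }
})

test_that("capacities are homogeneous of degree one in N_ps", {
  sp <- c4_archetype()
  alloc <- allocation(0.4, 0.1, 0.5, 0.8)
  c1 <- capacities(alloc, test_env(N_t = 100), sp)
  c2 <- capacities(alloc, test_env(N_t = 200), sp)
  for (fld in c("N_ps", "E_tot", "V_pmax", "Chl", "Jmax_LET", "Jmax_CET")) {
    expect_equal(c2[[fld]], 2 * c1[[fld]], tolerance = 1e-12, label = fld)
  }
})

test_that("allocation enforces the nitrogen sum and bounds", {
  expect_error(allocation(0.5, 0.2, 0.4, 0.9), "sum to 1")
  expect_error(allocation(-0.1, 0.5, 0.6, 0.9), "n_Etot")
  a <- allocation(0.5, 0.1, 0.4, 0.9)
  expect_s3_class(a, "photo_allocation")
  # degenerate single-pool allocations are allowed
  expect_silent(allocation(1, 0, 0, 0.5))
})

test_that("degenerate allocations produce zero capacities where expected", {
  sp <- c3_archetype()
  caps <- capacities(allocation(1, 0, 0, 0.95), test_env(), sp)
  expect_equal(caps$V_pmax, 0)
  expect_equal(caps$Jmax_LET, 0)
  expect_equal(caps$Jmax_CET, 0)
  expect_equal(caps$E_tot, caps$N_ps * 1.27e-3)
})
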