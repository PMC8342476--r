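# delta_n, residual scoring, scenario comparison, curves, synthetic data.

test_that("delta_n sums absolute pool differences and is symmetric", {
  a <- allocation(0.5, 0.1, 0.4, p = 0.9)
  expect_equal(delta_n(a, a)$delta_n, 0)
  b <- allocation(0.4, 0.2, 0.4, p = 0.7)
  d <- delta_n(a, b)
  expect_equal(d$delta_n, 0.2)
  expect_equal(unname(d$per_pool), c(0.1, 0.1, 0))
  expect_equal(sum(d$per_pool), d$delta_n)
  # p is excluded: allocations differing only in p have delta_n 0
  expect_equal(delta_n(a, allocation(0.5, 0.1, 0.4, p = 0.2))$delta_n, 0)
  set.seed(3)
  for (i in 1:20) {
    w1 <- stats::runif(3); w1 <- w1 / sum(w1)
    w2 <- stats::runif(3); w2 <- w2 / sum(w2)
    x <- allocation(w1[1], w1[2], w1[3], 0.5)
    y <- allocation(w2[1], w2[2], w2[3], 0.5)
    expect_equal(delta_n(x, y)$delta_n, delta_n(y, x)$delta_n)
    expect_gte(delta_n(x, y)$delta_n, 0)
    expect_lte(delta_n(x, y)$delta_n, 2)
  }
})

make_meas <- function(values, quantity = "A", x = seq_along(values)) {
  tibble::tibble(curve_id = "c", x_kind = "Ci", x_value = x,
                 quantity = quantity, value = values, se = NA_real_,
                 n = NA_integer_)
}

test_that("normalized squared residuals use fractions of experimental means", {
  m <- make_meas(c(1, 3))
  p <- make_meas(c(2, 2))
  r <- normalized_squared_residuals(p, m)
  expect_equal(r$r, c(0.25, 0.25))
  expect_equal(normalized_squared_residuals(m, m)$r, c(0, 0))
  # scale invariance
  r10 <- normalized_squared_residuals(make_meas(c(20, 20)), make_meas(c(10, 30)))
  expect_equal(r10$r, r$r)
  expect_error(normalized_squared_residuals(make_meas(c(1, 2, 3)), m), "match")
  expect_error(normalized_squared_residuals(make_meas(c(1, -1)),
                                            make_meas(c(1, -1))), "zero")
})

test_that("scenario comparison reproduces exact rank-sum and sign-test p-values", {
  r <- compare_scenarios(c(1, 2, 3), c(101, 102, 103))
  expect_equal(r$wilcoxon_p, 0.1)  # 2 / choose(6, 3)
  same <- compare_scenarios(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$wilcoxon_p, 1)
  pairs <- cbind(2:16, 1:15)  # 15 concordant pairs
  s <- compare_scenarios(c(1, 2), c(3, 4), delta_pairs = pairs)
  expect_equal(s$sign_p, 2 * 0.5^15)
  expect_equal(s$n_pairs, 15)
  expect_error(compare_scenarios(1, c(1, 2)), "at least two")
})

test_that("response curves sweep one axis at a fixed allocation", {
  sp <- c3_archetype()
  env <- test_env(I = 1000)
  alloc <- allocation(0.55, 0, 0.45, p = 0.95)
  part <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
  aci <- response_curves(sp, env, alloc, part, sweep = "Ci",
                         values = seq(50, 600, length.out = 12))
  expect_true(all(diff(aci$value) >= -1e-9))
  expect_equal(unique(aci$x_kind), "Ci")
  an <- response_curves(sp, env, alloc, part, sweep = "N",
                        values = c(0, 50, 130, 200))
  expect_equal(an$value[1], 0)
  expect_true(all(diff(an$value) >= -1e-9))
  at <- response_curves(sp, env, alloc, part, sweep = "T",
                        values = seq(10, 45, by = 1))
  i <- which.max(at$value)
  expect_gt(i, 1)
  expect_lt(i, nrow(at))
  expect_true(all(diff(at$value[1:i]) >= 0))
  expect_true(all(diff(at$value[i:nrow(at)]) <= 0))
  expect_error(response_curves(sp, env, alloc, part, sweep = "X", values = 1),
               "arg")
})

test_that("synthetic measurements are seeded, unbiased and correctly scaled", {
  sp <- c3_archetype()
  env <- test_env()
  alloc <- allocation(0.55, 0, 0.45, p = 0.95)
  part <- energy_partition(f_cb_m = 0.8, f_pr_m = 0.2)
  clean <- predict_pools(sp, env, alloc, part)
  noiseless <- synthetic_measurements(sp, env, alloc, part, noise_sd = 0)
  expect_equal(noiseless$value, clean$value)
  s1 <- synthetic_measurements(sp, env, alloc, part, noise_sd = 0.05, seed = 9)
  s2 <- synthetic_measurements(sp, env, alloc, part, noise_sd = 0.05, seed = 9)
  expect_identical(s1$value, s2$value)
  s3 <- synthetic_measurements(sp, env, alloc, part, noise_sd = 0.05, seed = 10)
  expect_false(identical(s1$value, s3$value))
  # Monte-Carlo: empirical SD of replicates within 5% of noise_sd * |value|
  base <- clean$value[clean$quantity == "A"]
  reps <- vapply(1:1000, function(s) {
    tb <- synthetic_measurements(table = clean[clean$quantity == "A", ],
                                 noise_sd = 0.05, seed = s)
    tb$value
  }, numeric(1))
  expect_equal(stats::sd(reps), 0.05 * abs(base), tolerance = 0.05)
  expect_equal(mean(reps), base, tolerance = 0.01)
})

test_that("measurement tables enforce the closed vocabulary", {
  bad <- tibble::tibble(curve_id = "c", x_kind = "Ci", x_value = 1,
                        quantity = "bogus", value = 1, se = 0, n = 1)
  expect_error(measurement_table(bad), "quantity")
  bad2 <- tibble::tibble(curve_id = "c", x_kind = "Z", x_value = 1,
                         quantity = "A", value = 1, se = 0, n = 1)
  expect_error(measurement_table(bad2), "x_kind")
  bad3 <- tibble::tibble(curve_id = "c", x_kind = "Ci", x_value = 1,
                         quantity = "A", value = 1, se = -1, n = 1)
  expect_error(measurement_table(bad3), "non-negative")
})

test_that("the environment scan recovers a generating cell from noiseless data", {
  sp <- c4_archetype()
  grid <- scan_predictions(sp, I_values = c(600, 1400), T_values = c(20, 32),
                           Cm_values = c(80, 200), N_t = 130, O = 200,
                           settings = optimizer_settings(n_starts = 3,
                                                         maxit = 300))
  gen <- 6L
  meas <- grid$prediction[[gen]]
  scan <- environment_scan(measured = meas, predictions = grid)
  expect_equal(scan$argmin_cell, gen)
  expect_equal(scan$argmin$error, 0, tolerance = 1e-12)
  expect_true(all(scan$surface$error >= 0, na.rm = TRUE))
  # rescaling all measurements of one quantity leaves the argmin stable
  meas2 <- meas
  meas2$value[meas2$quantity == "A"] <- meas2$value[meas2$quantity == "A"] * 1.02
  scan2 <- environment_scan(measured = meas2, predictions = grid)
  expect_equal(scan2$argmin_cell, gen)
})
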