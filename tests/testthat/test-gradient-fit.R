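test_that("trapezium weights integrate exactly on regular grids", {
  expect_equal(trapezium_weights(base::c(0, 0.5, 1)),
               base::c(0.25, 0.5, 0.25))
  g <- seq(0, 30, by = 0.5)
  expect_equal(sum(trapezium_weights(g)), 30)
  g1 <- seq(0, 1, by = 0.25)
  expect_equal(sum(trapezium_weights(g1) * rep(1, length(g1))), 1)
  expect_error(trapezium_weights(3), "at least 2")
  expect_error(trapezium_weights(base::c(0, 1, 3)), "uniformly spaced")
})

test_that("smooth_trajectory recovers a linear trend exactly", {
  tt <- base::c(0, 2, 5, 9, 14)
  sm <- smooth_trajectory(tt, 1 + 0.2 * tt)
  expect_lt(max(abs(sm$deriv - 0.2)), 1e-6)
  expect_lt(max(abs(sm$fitted - (1 + 0.2 * sm$times))), 1e-6)
  expect_lt(max(abs(sm$residuals)), 1e-8)
})

test_that("smooth_trajectory excludes degenerate trajectories with a warning", {
  expect_warning(out <- smooth_trajectory(base::c(0, 3, 7), base::c(1, 2, 3)),
                 "at least 5")
  expect_null(out)
  expect_error(smooth_trajectory(base::c(0, 2, 1, 4, 6), rep(1, 5)),
               "strictly increasing")
})

test_that("smoothed gradients track the growth equation on dense data", {
  truth <- scenario_truth("constant_rearing")
  sched <- allocation_schedule(seq(0, 60, 0.25),
                               true_r(truth, seq(0, 60, 0.25)))
  traj <- simulate_length(growth_params(0.169, 0.179), sched, 0.8, 60,
                          step = 0.05)
  tt <- 60 * seq(0, 1, length.out = 25)^1.6  # uneven, denser early
  l_obs <- stats::approx(traj$times, traj$lengths, xout = tt)$y
  sm <- smooth_trajectory(tt, l_obs, span = 0.3)
  l_true <- stats::approx(traj$times, traj$lengths, xout = sm$times)$y
  dl_true <- 0.169 * (1 - true_r(truth, sm$times)) * l_true^0.179
  expect_lt(max(abs(sm$deriv - dl_true)), 0.02 * dl_true[1])

  # the per-time WLS coefficient then reproduces q (1 - r_t)
  pg <- pergrid_coefficient(list(sm), 0.179)
  f_true <- 0.169 * (1 - true_r(truth, pg$times))
  expect_lt(max(abs(pg$f - f_true)), 0.03 * 0.169)
})

test_that("pergrid_coefficient handles degenerate and duplicated input", {
  flat <- structure(list(times = seq(0, 10, 0.5),
                         fitted = rep(2, 21), deriv = rep(0, 21),
                         weights = trapezium_weights(seq(0, 10, 0.5)),
                         residuals = numeric(0)),
                    class = "smoothed_trajectory")
  pg <- pergrid_coefficient(list(flat), 0.3)
  expect_true(all(pg$f == 0))
  expect_equal(pg$sse, 0)
  # duplicating a noise-free individual changes neither f_t nor the SSE
  tt <- base::c(0, 2, 4, 7, 9, 12, 15, 18, 22, 26, 30)
  ll <- bernoulli_length(tt, 0.8, 0.15, 0.2)
  sm <- smooth_trajectory(tt, ll)
  one <- pergrid_coefficient(list(sm), 0.2)
  two <- pergrid_coefficient(list(sm, sm), 0.2)
  expect_equal(two$f, one$f)
  expect_equal(two$sse, 2 * one$sse, tolerance = 1e-10)
})

test_that("profile_fit validates its lambda grid", {
  pop <- small_pop()
  expect_error(profile_fit(pop, lambda_grid = numeric(0)), "at least 3")
  expect_error(profile_fit(pop, lambda_grid = base::c(0.1, 0.2)),
               "at least 3")
  expect_error(profile_fit(pop, lambda_grid = base::c(0.2, 0.1, 0.3)),
               "strictly increasing")
})

test_that("profile_fit recovers a null allocation schedule", {
  fit <- suppressWarnings(profile_fit(null_allocation_pop(),
                                      lambda_grid = seq(0, 0.4, 0.02)))
  expect_lt(abs(fit$lambda_hat - 0.179), 0.03)
  expect_lt(abs(fit$q_hat[["null"]] / 0.12 - 1), 0.03)
  expect_lt(max(fit$r_hat$null$r), 0.05)
  expect_identical(fit$r_hat$null$r[1], 0)
})

test_that("the profiled objective is minimal at the returned lambda", {
  fit <- suppressWarnings(profile_fit(small_pop(),
                                      lambda_grid = seq(0, 0.5, 0.05)))
  expect_lte(fit$sse, min(fit$profile$sse) + 1e-9)
})

test_that("profile_fit is invariant to duplicating every individual", {
  pop <- small_pop()
  dup <- as.data.frame(pop)
  dup$individual_id <- paste0(dup$individual_id, "_copy")
  both <- growth_dataset(rbind(as.data.frame(pop), dup))
  f1 <- suppressWarnings(profile_fit(pop, lambda_grid = seq(0.05, 0.35, 0.05)))
  f2 <- suppressWarnings(profile_fit(both, lambda_grid = seq(0.05, 0.35, 0.05)))
  expect_equal(f2$lambda_hat, f1$lambda_hat, tolerance = 1e-6)
  expect_equal(f2$q_hat, f1$q_hat, tolerance = 5e-3)
})

test_that("rescaling lengths rescales q and leaves lambda and r alone", {
  pop <- small_pop()
  um <- as.data.frame(pop)
  um$length_mm <- um$length_mm * 1000
  pop_um <- growth_dataset(um)
  grid <- seq(0.05, 0.35, 0.05)
  f_mm <- suppressWarnings(profile_fit(pop, lambda_grid = grid))
  f_um <- suppressWarnings(profile_fit(pop_um, lambda_grid = grid))
  expect_equal(f_um$lambda_hat, f_mm$lambda_hat, tolerance = 1e-6)
  u <- 1000
  expect_equal(f_um$q_hat[["constant_rearing"]],
               f_mm$q_hat[["constant_rearing"]] * u^(1 - f_mm$lambda_hat),
               tolerance = 1e-4)
  expect_equal(f_um$r_hat$constant_rearing$r, f_mm$r_hat$constant_rearing$r,
               tolerance = 1e-4)
})

test_that("bootstrap_ci is deterministic and demands a seed", {
  pop <- small_pop()
  expect_error(bootstrap_ci(pop, B = 5), "seed")
  expect_error(bootstrap_ci(pop, B = 1, seed = 1), "at least 2")
  grid <- seq(0.05, 0.35, 0.05)
  b1 <- suppressWarnings(bootstrap_ci(pop, B = 8, seed = 42,
                                      lambda_grid = grid))
  b2 <- suppressWarnings(bootstrap_ci(pop, B = 8, seed = 42,
                                      lambda_grid = grid))
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci$q[, "lower"] <= b1$ci$q[, "upper"]))
})

test_that("a population of identical individuals has zero-width q intervals", {
  truth <- scenario_truth("constant_rearing")
  sched <- allocation_schedule(seq(0, 45, 0.25),
                               true_r(truth, seq(0, 45, 0.25)))
  traj <- simulate_length(growth_params(0.169, 0.179), sched, 0.8, 45)
  tt <- base::c(0, 5, 8, 11, 15, 19, 23, 28, 33, 39, 45)
  ll <- stats::approx(traj$times, traj$lengths, xout = tt)$y
  rows <- lapply(1:10, function(i)
    data.frame(individual_id = paste0("clone", i), scenario = "x",
               time_days = tt, length_mm = ll,
               neonates = base::c(NA, rep(3, 9), NA)[seq_along(tt)]))
  clones <- growth_dataset(do.call(rbind, rows))
  b <- suppressWarnings(bootstrap_ci(clones, B = 6, seed = 3,
                                     lambda_grid = seq(0.1, 0.3, 0.05)))
  expect_lt(diff(b$ci$q["x", ]), 1e-10)
})
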