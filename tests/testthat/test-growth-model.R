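test_that("lambda/alpha conversions match the cubic-scaling identities", {
  # von Bertalanffy exponent 2/3 maps to lambda = 0 under cubic scaling
  expect_equal(lambda_from_alpha(2 / 3, 3), 0)
  expect_equal(lambda_from_alpha(1, 3), 1)
  expect_equal(alpha_from_lambda(1, 5), 1)
  expect_equal(alpha_from_lambda(0, 3), 2 / 3)
  # the fitted length exponent 0.179 corresponds to a mass exponent 0.726
  expect_equal(round(alpha_from_lambda(0.179, 3), 3), 0.726)
  expect_equal(round(lambda_from_alpha(0.7263333, 3), 3), 0.179)
  # round trip to machine precision
  for (al in base::c(-0.3, 0.5, 2 / 3, 0.9, 1.4))
    expect_equal(alpha_from_lambda(lambda_from_alpha(al, 3), 3), al)
  expect_error(lambda_from_alpha(NA_real_, 3))
  expect_error(alpha_from_lambda(0.2, 0))
  expect_error(lambda_from_alpha(0.7, -1))
})

test_that("simulate_length matches closed forms without reproduction", {
  # lambda = 0: linear growth
  tr <- simulate_length(growth_params(0.2, 0), NULL, 1, 10, step = 0.1)
  expect_equal(tr$lengths, 1 + 0.2 * tr$times, tolerance = 1e-10)
  # lambda = 1: exponential growth
  tr <- simulate_length(growth_params(0.05, 1), NULL, 1.5, 10, step = 0.1)
  expect_equal(tr$lengths, 1.5 * exp(0.05 * tr$times), tolerance = 1e-8)
  # generic lambda: Bernoulli closed form, including the fitted value 0.179
  for (lam in base::c(-0.5, 0, 0.179, 0.5)) {
    tr <- simulate_length(growth_params(0.169, lam), NULL, 0.8, 60,
                          step = 0.1)
    cf <- bernoulli_length(tr$times, 0.8, 0.169, lam)
    expect_lt(max(abs(tr$lengths - cf) / cf), 1e-8)
  }
})

test_that("simulate_length halving the step shrinks the endpoint error ~16x", {
  closed <- bernoulli_length(40, 0.8, 0.169, 0.5)
  err <- vapply(base::c(0.4, 0.2), function(st) {
    tr <- simulate_length(growth_params(0.169, 0.5), NULL, 0.8, 40, step = st)
    abs(utils::tail(tr$lengths, 1) - closed)
  }, numeric(1))
  expect_gt(err[1] / err[2], 8)   # 4th-order convergence (allow slack)
})

test_that("simulate_length is nondecreasing and rejects r >= 1", {
  sched <- allocation_schedule(base::c(0, 10, 40), base::c(0, 0.6, 0.95))
  tr <- simulate_length(growth_params(0.2, 0.3), sched, 0.8, 50)
  expect_true(all(diff(tr$lengths) >= 0))
  bad <- allocation_schedule(base::c(0, 5), base::c(0, 0.999999999))
  bad$r[2] <- 1.2  # corrupt past the constructor to exercise the solver guard
  expect_error(simulate_length(growth_params(0.2, 0.3), bad, 0.8, 10),
               "r_t >= 1")
})

test_that("allocation_schedule enforces its invariants", {
  expect_error(allocation_schedule(base::c(1, 2), base::c(0, 0.5)),
               "start at time 0")
  expect_error(allocation_schedule(base::c(0, 2), base::c(0.1, 0.5)),
               "time 0")
  expect_silent(allocation_schedule(base::c(0, 2), base::c(0.1, 0.5),
                                    r0_zero = FALSE))
  expect_error(allocation_schedule(base::c(0, 2, 2), base::c(0, 0.1, 0.2)),
               "strictly increasing")
  expect_error(allocation_schedule(base::c(0, 2), base::c(0, 1)),
               "\\[0, 1\\)")
})

test_that("simulate_mass conserves mass and resets gonads at broods", {
  mp <- mass_params(a = 1, alpha = 0.7, b = 0.12, beta = 0.8, c = 0.2,
                    gamma = 0.9)
  mt <- simulate_mass(mp, s0 = 0.1, brood_times = base::c(10, 20), t_end = 30,
                      step = 0.05)
  expect_lt(max(abs(mt$total - (mt$somatic + mt$gonadic)) / mt$total), 1e-9)
  expect_equal(mt$gonadic[1], 0)
  # g accumulates to the brood, then restarts from 0 just after it
  i10 <- which(mt$times == 10)
  expect_gt(mt$gonadic[i10], 0)
  expect_lt(mt$gonadic[i10 + 1], mt$gonadic[i10])
  expect_true(all(diff(mt$somatic) > 0))
})

test_that("simulate_mass reduces to Puetter form when b = 0", {
  mp <- mass_params(a = 1, alpha = 2 / 3, b = 0, beta = 0.8, c = 0.3,
                    gamma = 1)
  mt <- simulate_mass(mp, s0 = 0.05, t_end = 20, step = 0.05)
  expect_true(all(mt$gonadic == 0))
  expect_equal(mt$total, mt$somatic)
})

test_that("equal exponents give constant allocation dg/dm = b/(a-c)", {
  mp <- mass_params(a = 1.5, alpha = 0.75, b = 0.3, beta = 0.75, c = 0.4,
                    gamma = 0.75)
  mt <- simulate_mass(mp, s0 = 0.2, t_end = 15, step = 0.01)
  ratio <- diff(mt$gonadic) / diff(mt$total)
  expect_lt(max(abs(ratio - 0.3 / (1.5 - 0.4))), 1e-10)
})

test_that("simulate_mass rejects shrinkage and out-of-range broods", {
  mp <- mass_params(a = 0.1, alpha = 0.7, b = 0.05, beta = 0.7, c = 0.5,
                    gamma = 1)
  expect_error(simulate_mass(mp, s0 = 1, t_end = 10), "shrinkage")
  ok <- mass_params(a = 1, alpha = 0.7, b = 0.1, beta = 0.8, c = 0.2,
                    gamma = 0.9)
  expect_error(simulate_mass(ok, s0 = 0.1, brood_times = 50, t_end = 10),
               "brood_times")
})

test_that("mass and length models agree under the parameter map", {
  # with alpha = gamma the mass system maps exactly onto the length
  # equation via q = (h^(alpha-1)/k)(a - c), lambda = k(alpha-1)+1 and the
  # r_t computed from the mass trajectory
  mp <- mass_params(a = 1, alpha = 0.726, b = 0.15, beta = 0.8, c = 0.25,
                    gamma = 0.726)
  h <- 0.08; k <- 3
  mt <- simulate_mass(mp, s0 = 0.05, t_end = 40, step = 0.02)
  r_path <- relative_fecundity_rate(mp, mt$somatic)
  sched <- allocation_schedule(mt$times, pmin(r_path, 1 - 1e-9),
                               r0_zero = FALSE)
  q <- h^(mp$alpha - 1) / k * (mp$a - mp$c)
  lam <- lambda_from_alpha(mp$alpha, k)
  lt <- simulate_length(growth_params(q, lam), sched,
                        l0 = (0.05 / h)^(1 / k), t_end = 40, step = 0.02)
  l_implied <- mass_length_convert(length_scale(h, k), mt$somatic,
                                   "mass_to_length")
  expect_lt(max(abs(lt$lengths - l_implied) / l_implied), 1e-6)
})

test_that("relative_fecundity_rate matches definitions and finite differences", {
  mp <- mass_params(a = 1.5, alpha = 0.75, b = 0.3, beta = 0.75, c = 0.4,
                    gamma = 0.75)
  expect_equal(relative_fecundity_rate(mp, 0.37), 0.3 / (1.5 - 0.4))
  expect_equal(relative_fecundity_rate(mp, 5), 0.3 / (1.5 - 0.4))
  mp0 <- mass_params(a = 1, alpha = 0.7, b = 0, beta = 0.8, c = 0.2,
                     gamma = 0.9)
  expect_equal(relative_fecundity_rate(mp0, 2), 0)
  # finite-difference oracle on the simulated trajectory
  mp2 <- mass_params(a = 1.2, alpha = 0.7, b = 0.2, beta = 0.85, c = 0.3,
                     gamma = 0.9)
  mt <- simulate_mass(mp2, s0 = 0.1, t_end = 2e-4, step = 1e-4)
  fd <- diff(mt$gonadic)[1] / diff(mt$total)[1]
  expect_lt(abs(fd / relative_fecundity_rate(mp2, 0.1) - 1), 1e-3)
  # inadmissible states raise rather than returning r outside [0, 1)
  heavy <- mass_params(a = 1, alpha = 0.7, b = 0.05, beta = 0.7, c = 0.9,
                       gamma = 0.7)
  expect_error(relative_fecundity_rate(
    mass_params(a = 1, alpha = 0.7, b = 0.1, beta = 0.7, c = 1.5,
                gamma = 0.7), 1), "dm")
  expect_error(relative_fecundity_rate(
    mass_params(a = 1, alpha = 0.7, b = 0.9, beta = 0.7, c = 0.2,
                gamma = 0.7), 1), "r_t >= 1")
  expect_lt(relative_fecundity_rate(heavy, 1), 1)
})

test_that("maintenance_fraction follows (c/a) s^(gamma-alpha)", {
  mp <- mass_params(a = 1, alpha = 0.7, b = 0.1, beta = 0.8, c = 0.3,
                    gamma = 0.7)
  expect_equal(maintenance_fraction(mp, 0.01), 0.3)
  expect_equal(maintenance_fraction(mp, 100), 0.3)
  mp0 <- mass_params(a = 1, alpha = 0.7, b = 0.1, beta = 0.8, c = 0,
                     gamma = 1)
  expect_equal(maintenance_fraction(mp0, 3), 0)
  mp2 <- mass_params(a = 1, alpha = 0.7, b = 0.05, beta = 0.8, c = 0.2,
                     gamma = 0.8)
  expect_equal(maintenance_fraction(mp2, exp(10)), 0.2 * exp(1),
               tolerance = 1e-12)
})

test_that("mass_length_convert applies s = h l^k and round-trips", {
  sc <- length_scale(1, 3)
  expect_equal(mass_length_convert(sc, 2, "length_to_mass"), 8)
  sc2 <- length_scale(0.05, 3)
  expect_equal(mass_length_convert(sc2, 0.4, "mass_to_length"), 2)
  set.seed(3)
  x <- stats::runif(20, 0.1, 5)
  back <- mass_length_convert(sc2, mass_length_convert(sc2, x,
                                                       "length_to_mass"),
                              "mass_to_length")
  expect_equal(back, x, tolerance = 1e-12)
  expect_error(mass_length_convert(sc, -1, "length_to_mass"), "positive")
})
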