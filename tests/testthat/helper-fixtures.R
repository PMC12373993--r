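# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the default four-scenario synthetic study and its gradient-matching fit
acc_study <- function() fixture("acc_study", function() generate_study(seed = 1))
acc_fit <- function() fixture("acc_fit", function()
  suppressWarnings(profile_fit(acc_study())))
acc_summary <- function() fixture("acc_summary", function()
  lifetime_summary(acc_fit(), acc_study()))

# a small single-scenario population for unit-scale checks
small_pop <- function() fixture("small_pop", function()
  generate_population(scenario_truth("constant_rearing"), 40, seed = 7))

# a noise-free dataset generated under r == 0 (pure power-law growth),
# lengths from the Bernoulli closed form at q = 0.12, lambda = 0.179
null_allocation_pop <- function(n = 25, seed = 9) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    l0 <- stats::rlnorm(1, log(0.8), 0.08)
    life <- stats::runif(1, 50, 70)
    tt <- sort(base::c(0, stats::runif(14, 3, life), life))
    ll <- (l0^(1 - 0.179) + (1 - 0.179) * 0.12 * tt)^(1 / (1 - 0.179))
    data.frame(individual_id = sprintf("i%02d", i), scenario = "null",
               time_days = tt, length_mm = ll, neonates = NA_real_)
  })
  growth_dataset(do.call(rbind, rows))
}

# closed-form solution of dl = q (1 - r) l^lambda with constant r
bernoulli_length <- function(t, l0, q, lambda, r = 0) {
  if (lambda == 1) return(l0 * exp(q * (1 - r) * t))
  (l0^(1 - lambda) + (1 - lambda) * q * (1 - r) * t)^(1 / (1 - lambda))
}
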