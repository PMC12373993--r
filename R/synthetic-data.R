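# Synthetic Daphnia-style cohorts with known ground truth: four temperature
# scenarios, event-driven observation times (birth, broods, death), noisy
# lengths and Poisson neonate counts.

scenario_labels <- base::c("constant_low", "constant_rearing",
                           "constant_high", "unpredictable")

# default cohort sizes of the emulated four-scenario study
default_cohorts <- base::c(constant_low = 158, constant_rearing = 156,
                           constant_high = 157, unpredictable = 157)

#' Ground-truth parameter set for a temperature scenario
#'
#' Returns the generator's defaults for one of the four temperature
#' scenarios (constant 15, 20 or 25 degrees C, or unpredictable variation
#' within 15--25 degrees C). The growth scalar `q`, the shared exponent
#' `lambda`, the mean lifespans and the lifetime neonate totals are
#' calibrated to the fitted values reported for the emulated experiment;
#' the reproduction-investment schedule is the saturating exponential
#' `r(t) = r_max (1 - exp(-t / theta))`, rising faster (smaller `theta`)
#' at warmer temperatures. The neonate rate (neonates per unit reproduction
#' energy) is derived at construction so that the expected lifetime neonate
#' count at the mean lifespan matches the scenario's target total.
#'
#' @param label One of `"constant_low"`, `"constant_rearing"`,
#'   `"constant_high"`, `"unpredictable"`.
#'
#' @return An object of class `scenario_truth` with fields `label`,
#'   `q_true`, `lambda_true`, `r_max`, `theta`, `mean_lifespan`,
#'   `lifespan_cv`, `maturation_days`, `maturation_cv`, `brood_interval`,
#'   `brood_interval_cv`, `l0_mean`, `l0_cv`, `obs_noise_cv` and
#'   `neonate_rate`.
#' @export
#' @examples
#' scenario_truth("constant_low")$q_true  # 0.118
scenario_truth <- function(label = scenario_labels) {
  label <- match.arg(label)
  defaults <- list(
    constant_low = list(q_true = 0.118, mean_lifespan = 81,
                        r_max = 0.70, theta = 12, maturation_days = 8,
                        brood_interval = 4.0, n_total = 239),
    constant_rearing = list(q_true = 0.169, mean_lifespan = 72,
                            r_max = 0.72, theta = 8, maturation_days = 6,
                            brood_interval = 3.5, n_total = 236),
    constant_high = list(q_true = 0.209, mean_lifespan = 48,
                         r_max = 0.78, theta = 5, maturation_days = 4.5,
                         brood_interval = 2.5, n_total = 181),
    unpredictable = list(q_true = 0.196, mean_lifespan = 52,
                         r_max = 0.76, theta = 5.5, maturation_days = 5,
                         brood_interval = 2.8, n_total = 194))[[label]]
  truth <- structure(
    list(label = label, q_true = defaults$q_true, lambda_true = 0.179,
         r_max = defaults$r_max, theta = defaults$theta,
         mean_lifespan = defaults$mean_lifespan, lifespan_cv = 0.30,
         maturation_days = defaults$maturation_days, maturation_cv = 0.15,
         brood_interval = defaults$brood_interval,
         brood_interval_cv = 0.15,
         l0_mean = 0.8, l0_cv = 0.08, obs_noise_cv = 0.01,
         neonate_rate = NA_real_),
    class = "scenario_truth")
  # calibrate neonates-per-energy so E[N(mean lifespan)] hits the target
  g_tau <- true_cumulative_energy(truth, truth$mean_lifespan)
  truth$neonate_rate <- defaults$n_total / utils::tail(g_tau$g, 1)
  truth
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf("Scenario truth '%s':\n", x$label))
  cat(sprintf("  q = %g, lambda = %g, r(t) = %g (1 - exp(-t/%g))\n",
              x$q_true, x$lambda_true, x$r_max, x$theta))
  cat(sprintf("  lifespan ~ Gamma(mean %g d, cv %g); first brood %g d (cv %g), then every %g d (cv %g)\n",
              x$mean_lifespan, x$lifespan_cv, x$maturation_days,
              x$maturation_cv, x$brood_interval, x$brood_interval_cv))
  cat(sprintf("  l0 ~ lognormal(%g mm, cv %g); length noise cv %g; %0.3g neonates per energy unit\n",
              x$l0_mean, x$l0_cv, x$obs_noise_cv, x$neonate_rate))
  invisible(x)
}

# true r(t) schedule of a scenario on a dense grid up to t_end
truth_schedule <- function(truth, t_end, by = 0.1) {
  tt <- seq(0, max(t_end, by), by = by)
  if (utils::tail(tt, 1) < t_end) tt <- base::c(tt, t_end)
  allocation_schedule(tt, truth$r_max * (1 - exp(-tt / truth$theta)))
}

#' True reproduction-investment rate of a scenario
#'
#' Evaluates the generator's ground-truth schedule
#' `r(t) = r_max (1 - exp(-t / theta))`.
#'
#' @param truth A [scenario_truth()].
#' @param t Ages in days.
#' @return `r(t)` values.
#' @export
true_r <- function(truth, t) {
  stopifnot(inherits(truth, "scenario_truth"))
  truth$r_max * (1 - exp(-t / truth$theta))
}

# true length curve and cumulative reproduction energy q int r l^lambda
# for one individual (or the scenario mean when l0 omitted)
true_cumulative_energy <- function(truth, t_end, l0 = truth$l0_mean,
                                   step = 0.05) {
  sched <- truth_schedule(truth, t_end)
  traj <- simulate_length(growth_params(truth$q_true, truth$lambda_true),
                          sched, l0 = l0, t_end = t_end, step = step)
  integrand <- truth$q_true * true_r(truth, traj$times) *
    traj$lengths^truth$lambda_true
  list(times = traj$times, lengths = traj$lengths,
       g = cumtrapz(traj$times, integrand))
}

# lognormal draws with a given mean and coefficient of variation
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic population for one scenario
#'
#' Simulates `n_individuals` life histories under a scenario's ground truth:
#' birth length drawn lognormal, lifespan drawn gamma, the true length curve
#' integrated from the growth equation at the true `(q, lambda, r_t)`,
#' brood times starting at an individually drawn maturation age followed by
#' individually jittered inter-brood intervals (so observation designs vary
#' between individuals, as they do in a real cohort), observations only at
#' birth, broods and death (uneven, event-driven times), multiplicative
#' lognormal measurement noise on lengths, and Poisson neonate counts with
#' mean proportional to the reproduction-energy increment accrued since the
#' previous brood.
#'
#' @param truth A [scenario_truth()] (or a modified copy).
#' @param n_individuals Number of individuals, `>= 1`.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A [growth_dataset()] with the scenario's truth attached as
#'   attribute `"truth"`.
#' @export
#' @examples
#' pop <- generate_population(scenario_truth("constant_high"), 5, seed = 42)
#' head(pop)
generate_population <- function(truth, n_individuals, seed) {
  stopifnot(inherits(truth, "scenario_truth"))
  if (n_individuals < 1) stop("'n_individuals' must be >= 1")
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (truth$r_max < 0 || truth$r_max >= 1 || truth$theta <= 0 ||
      truth$brood_interval <= 0 || truth$lifespan_cv < 0 ||
      truth$l0_cv < 0 || truth$obs_noise_cv < 0)
    stop("invalid scenario truth")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  shape <- 1 / truth$lifespan_cv^2
  rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    l0 <- rlnorm_cv(1, truth$l0_mean, truth$l0_cv)
    lifespan <- if (truth$lifespan_cv == 0) truth$mean_lifespan else
      stats::rgamma(1, shape = shape, rate = shape / truth$mean_lifespan)
    lifespan <- max(lifespan, 2)  # a life shorter than 2 days is not observed
    path <- true_cumulative_energy(truth, lifespan, l0 = l0)
    broods <- numeric(0)
    t_brood <- rlnorm_cv(1, truth$maturation_days, truth$maturation_cv)
    while (t_brood < lifespan - 1e-6) {
      broods <- base::c(broods, t_brood)
      t_brood <- t_brood + rlnorm_cv(1, truth$brood_interval,
                                     truth$brood_interval_cv)
    }
    obs_t <- base::c(0, broods, lifespan)
    true_l <- stats::approx(path$times, path$lengths, xout = obs_t)$y
    obs_l <- true_l * rlnorm_cv(length(obs_t), 1, truth$obs_noise_cv)
    g_at <- stats::approx(path$times, path$g, xout = obs_t)$y
    counts <- rep(NA_real_, length(obs_t))
    if (length(broods)) {
      dg <- diff(g_at)[seq_along(broods)]  # energy since previous event
      counts[seq_along(broods) + 1L] <- stats::rpois(length(broods),
                                                     truth$neonate_rate * dg)
    }
    rows[[i]] <- data.frame(
      individual_id = sprintf("%s_%03d", truth$label, i),
      scenario = truth$label, time_days = obs_t, length_mm = obs_l,
      neonates = counts)
  }
  out <- growth_dataset(do.call(rbind, rows))
  attr(out, "truth") <- truth
  out
}

#' Generate the default four-scenario synthetic study
#'
#' Simulates all four temperature scenarios at their default cohort sizes
#' (158 constant-low, 156 constant-rearing, 157 constant-high and 157
#' unpredictable individuals; 628 in total) with per-scenario seeds derived
#' from `seed`.
#'
#' @param seed Integer seed.
#' @param n_per_scenario Named integer vector of cohort sizes (defaults
#'   above); names must be the scenario labels.
#' @return A [growth_dataset()] with attribute `"truth"`, a named list of
#'   the four [scenario_truth()] objects.
#' @export
generate_study <- function(seed, n_per_scenario = default_cohorts) {
  if (missing(seed)) stop("'seed' is required")
  if (is.null(names(n_per_scenario)) ||
      !all(names(n_per_scenario) %in% scenario_labels))
    stop("'n_per_scenario' must be named by scenario label")
  parts <- list(); truths <- list()
  for (j in seq_along(n_per_scenario)) {
    label <- names(n_per_scenario)[j]
    truth <- scenario_truth(label)
    sub_seed <- (seed * 97L + j * 1009L) %% .Machine$integer.max
    parts[[label]] <- generate_population(truth, n_per_scenario[[j]],
                                          seed = sub_seed)
    truths[[label]] <- truth
  }
  out <- growth_dataset(do.call(rbind, lapply(parts, as.data.frame)))
  attr(out, "truth") <- truths
  out
}

#' Temperature schedule of a scenario
#'
#' Constant scenarios hold 15, 20 or 25 degrees C. Under the unpredictable
#' scenario the temperature is redrawn uniformly at each resolution step
#' within the segment's band: 15--20 degrees C from 00:00--08:00 and
#' 18:00--24:00, and 20--25 degrees C from 08:00--18:00. With independent
#' uniform draws the long-run mean is (14 x 17.5 + 10 x 22.5) / 24, about
#' 19.58 degrees C.
#'
#' @param label Scenario label.
#' @param n_days Number of days, `>= 1`.
#' @param resolution_hours Draw interval in hours; must divide 24.
#' @param seed Integer seed (required for the unpredictable scenario).
#'
#' @return An object of class `temperature_series`: a data frame with
#'   `hour` (since the experiment start) and `temp_c`.
#' @export
temperature_schedule <- function(label = scenario_labels, n_days,
                                 resolution_hours = 1, seed = NULL) {
  label <- match.arg(label)
  if (n_days < 1) stop("'n_days' must be >= 1")
  if (24 %% resolution_hours != 0)
    stop("'resolution_hours' must divide 24")
  hours <- seq(0, n_days * 24 - resolution_hours, by = resolution_hours)
  if (label != "unpredictable") {
    temp <- switch(label, constant_low = 15, constant_rearing = 20,
                   constant_high = 25)
    temp <- rep(temp, length(hours))
  } else {
    if (is.null(seed)) stop("'seed' is required for the unpredictable scenario")
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    tod <- hours %% 24
    day_seg <- tod >= 8 & tod < 18
    temp <- numeric(length(hours))
    temp[day_seg] <- stats::runif(sum(day_seg), 20, 25)
    temp[!day_seg] <- stats::runif(sum(!day_seg), 15, 20)
  }
  structure(data.frame(hour = hours, temp_c = temp),
            class = base::c("temperature_series", "data.frame"))
}
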