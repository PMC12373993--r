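# Lifetime fecundity: cumulative reproduction-energy curve
# g_tau = q int_0^tau r_u l_u^lambda du, scaled to observed neonate counts.

#' Cumulative reproduction-energy curve for a fitted scenario
#'
#' Integrates `q r_u l_u^lambda` from birth to each point of `tau_grid`,
#' where `l_u` is the model-implied length curve (the numerical solution of
#' the growth equation at the fitted parameters, started from the scenario's
#' mean observed birth length) and `r_u` the fitted reproduction-investment
#' schedule. The result is the cumulative energy allocated to direct
#' reproduction, in arbitrary units, to be scaled to neonate counts with
#' [scale_to_counts()].
#'
#' @param fit A `growth_fit` from [profile_fit()].
#' @param scenario Scenario label present in `fit`.
#' @param tau_grid Increasing age grid (days) starting at 0; default is the
#'   fitted `r_t` grid for the scenario. Ages beyond the fitted support use
#'   constant-`r` extrapolation, with a warning.
#' @param l0 Birth length (mm) for the model curve; default is the
#'   scenario's mean observed birth length stored in the fit.
#'
#' @return An object of class `fecundity_curve`: `tau_grid`, `g` (cumulative
#'   energy, `g(0) = 0`), `scale_const` (`NA` until scaled), `n_hat`
#'   (`NULL` until scaled), `scenario` and the model length curve `l`.
#' @export
cumulative_reproduction <- function(fit, scenario, tau_grid = NULL,
                                    l0 = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!scenario %in% names(fit$r_hat))
    stop("scenario '", scenario, "' not present in the fit")
  sched <- fit$r_hat[[scenario]]
  if (is.null(tau_grid)) tau_grid <- sched$times
  if (tau_grid[1] != 0 || any(diff(tau_grid) <= 0))
    stop("'tau_grid' must start at 0 and be strictly increasing")
  if (max(tau_grid) > max(sched$times) + 1e-8)
    warning("tau beyond the fitted r_t support; ",
            "extrapolating with the last r value")
  if (is.null(l0)) {
    info <- fit$scenario_info[[scenario]]
    if (is.null(info))
      stop("no birth-length information in the fit; supply 'l0'")
    l0 <- info$l0
  }
  params <- growth_params(fit$q_hat[[scenario]], fit$lambda_hat)
  step <- min(0.05, diff(tau_grid))
  traj <- simulate_length(params, sched, l0 = l0, t_end = max(tau_grid),
                          step = step)
  lfun <- stats::approxfun(traj$times, traj$lengths, rule = 2)
  rfun <- schedule_fun(sched)
  integrand <- params$q * rfun(tau_grid) * lfun(tau_grid)^params$lambda
  g <- cumtrapz(tau_grid, integrand)
  structure(list(tau_grid = tau_grid, g = g, scale_const = NA_real_,
                 n_hat = NULL, scenario = scenario,
                 l = lfun(tau_grid)),
            class = "fecundity_curve")
}

# cumulative trapezium integral along (possibly nonuniform) x
cumtrapz <- function(x, y) {
  n <- length(x)
  base::c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' @export
print.fecundity_curve <- function(x, ...) {
  cat(sprintf("Fecundity curve (%s): %d points on [0, %g] days\n",
              x$scenario, length(x$tau_grid), max(x$tau_grid)))
  if (!is.na(x$scale_const))
    cat(sprintf("  scaled: %.4g neonates per energy unit, N(end) = %.1f\n",
                x$scale_const, utils::tail(x$n_hat, 1)))
  else cat("  unscaled (energy units)\n")
  invisible(x)
}

#' Scale a reproduction-energy curve to neonate counts
#'
#' Fits the proportionality constant between cumulative reproduction energy
#' and the cumulative number of neonates by least squares through the
#' origin, pooling every (individual, brood) pair in the scenario:
#' `c = sum(N_obs * g) / sum(g^2)`, where `N_obs(i, t)` is individual `i`'s
#' cumulative neonate count at brood time `t` and `g(t)` the curve value.
#'
#' @param curve A [cumulative_reproduction()] result.
#' @param dataset The [growth_dataset()] holding the brood records.
#' @param scenario Scenario label; default the curve's own.
#'
#' @return The curve with `scale_const` set and `n_hat = scale_const * g`.
#' @export
scale_to_counts <- function(curve, dataset, scenario = curve$scenario) {
  stopifnot(inherits(curve, "fecundity_curve"),
            inherits(dataset, "growth_dataset"))
  rows <- dataset[dataset$scenario == scenario & !is.na(dataset$neonates) &
                    dataset$time_days > 0, , drop = FALSE]
  if (!nrow(rows))
    stop("no brood records in scenario '", scenario, "'")
  cum_by_id <- lapply(split(rows, rows$individual_id), function(d) {
    d <- d[order(d$time_days), , drop = FALSE]
    data.frame(time_days = d$time_days, n_cum = cumsum(d$neonates))
  })
  obs <- do.call(rbind, cum_by_id)
  gfun <- stats::approxfun(curve$tau_grid, curve$g, rule = 2)
  g_at <- gfun(obs$time_days)
  if (all(g_at == 0))
    stop("cumulative energy is zero at every brood time; cannot scale")
  const <- sum(obs$n_cum * g_at) / sum(g_at^2)
  curve$scale_const <- const
  curve$n_hat <- const * curve$g
  curve
}

#' Mean lifespan of a scenario
#'
#' Arithmetic mean of the per-individual death times (each individual's last
#' observation time).
#'
#' @param dataset A [growth_dataset()].
#' @param scenario Scenario label.
#' @return Mean lifespan in days.
#' @export
mean_lifetime <- function(dataset, scenario) {
  mean(death_times(dataset, scenario))
}

#' Evaluate the scaled neonate curve at an age
#'
#' Linear interpolation of the scaled cumulative neonate curve `N_hat` at
#' age `tau`; ages beyond the grid end are held at the last value, with a
#' warning.
#'
#' @param curve A scaled [fecundity_curve] (see [scale_to_counts()]).
#' @param tau Age in days, `>= 0`.
#' @return The interpolated cumulative neonate count.
#' @export
neonates_at <- function(curve, tau) {
  stopifnot(inherits(curve, "fecundity_curve"))
  if (is.null(curve$n_hat))
    stop("curve is unscaled; call scale_to_counts() first")
  if (any(tau < 0)) stop("'tau' must be nonnegative")
  if (any(tau > max(curve$tau_grid) + 1e-8))
    warning("tau beyond the curve's grid; holding the last value")
  stats::approx(curve$tau_grid, curve$n_hat, xout = tau, rule = 2)$y
}

#' Per-scenario lifetime summary table
#'
#' Builds the per-scenario summary of a growth fit: the growth scalar
#' `q_hat`, the shared exponent `lambda_hat`, the mean lifespan `tau_hat`
#' and the scaled cumulative neonate count at the mean lifespan `n_tau`.
#'
#' @param fit A `growth_fit` (optionally with bootstrap `ci`).
#' @param dataset The [growth_dataset()] the fit was computed from.
#' @param scale Either `"per_scenario"` (default; the proportionality
#'   constant between energy and neonate count is fitted within each
#'   scenario) or `"shared"` (one constant pooled across scenarios).
#'
#' @return A data frame with one row per scenario: `scenario`, `q_hat`,
#'   `lambda_hat`, `n_tau`, `tau_hat`, `scale_const`, and interval columns
#'   when the fit carries bootstrap results.
#' @export
lifetime_summary <- function(fit, dataset,
                             scale = c("per_scenario", "shared")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "growth_fit"))
  scenarios <- names(fit$q_hat)
  curves <- lapply(scenarios, function(sc)
    cumulative_reproduction(fit, sc))
  names(curves) <- scenarios
  if (scale == "per_scenario") {
    curves <- lapply(scenarios, function(sc)
      scale_to_counts(curves[[sc]], dataset, sc))
    names(curves) <- scenarios
  } else {
    # one constant across scenarios: pool numerator and denominator
    num <- 0; den <- 0
    for (sc in scenarios) {
      rows <- dataset[dataset$scenario == sc & !is.na(dataset$neonates) &
                        dataset$time_days > 0, , drop = FALSE]
      if (!nrow(rows)) next
      cum <- do.call(rbind, lapply(split(rows, rows$individual_id),
                                   function(d) {
                                     d <- d[order(d$time_days), , drop = FALSE]
                                     data.frame(t = d$time_days,
                                                n = cumsum(d$neonates))
                                   }))
      g_at <- stats::approx(curves[[sc]]$tau_grid, curves[[sc]]$g,
                            xout = cum$t, rule = 2)$y
      num <- num + sum(cum$n * g_at)
      den <- den + sum(g_at^2)
    }
    if (den == 0) stop("no brood records; cannot scale")
    const <- num / den
    for (sc in scenarios) {
      curves[[sc]]$scale_const <- const
      curves[[sc]]$n_hat <- const * curves[[sc]]$g
    }
  }
  tau <- vapply(scenarios, function(sc) mean_lifetime(dataset, sc),
                numeric(1))
  n_tau <- vapply(scenarios, function(sc)
    neonates_at(curves[[sc]], min(tau[[sc]], max(curves[[sc]]$tau_grid))),
    numeric(1))
  out <- data.frame(scenario = scenarios,
                    q_hat = unname(fit$q_hat[scenarios]),
                    lambda_hat = fit$lambda_hat,
                    n_tau = unname(n_tau),
                    tau_hat = unname(tau),
                    scale_const = vapply(curves, `[[`, numeric(1),
                                         "scale_const"),
                    row.names = NULL)
  if (!is.null(fit$ci)) {
    out$q_lower <- fit$ci$q[out$scenario, "lower"]
    out$q_upper <- fit$ci$q[out$scenario, "upper"]
    out$lambda_lower <- fit$ci$lambda[1]
    out$lambda_upper <- fit$ci$lambda[2]
    out$n_tau_lower <- fit$ci$n_tau[out$scenario, "lower"]
    out$n_tau_upper <- fit$ci$n_tau[out$scenario, "upper"]
    out$tau_lower <- fit$ci$tau[out$scenario, "lower"]
    out$tau_upper <- fit$ci$tau[out$scenario, "upper"]
  }
  attr(out, "curves") <- curves
  out
}
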