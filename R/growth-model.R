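# Core allometric growth model: coupled somatic/gonadic body-mass ODEs and
# their reduction to a single body-length equation dl = q (1 - r_t) l^lambda dt.

#' Body-mass model parameters
#'
#' Parameters of the allometric body-mass system in which the total-mass
#' increment `dm = ds + dg` splits into somatic growth
#' `ds = (a s^alpha - c s^gamma - b s^beta) dt` and gonadic growth
#' `dg = b s^beta dt`. The `a` term is energy acquisition, the `c` term the
#' non-growth (maintenance and indirect reproduction) cost and the `b` term
#' direct reproduction investment.
#'
#' @param a Energy-acquisition multiplier (mass^(1-alpha) per day), `> 0`.
#' @param alpha Acquisition exponent (dimensionless).
#' @param b Gonadic multiplier (mass^(1-beta) per day), `>= 0`.
#' @param beta Gonadic exponent.
#' @param c Non-growth-cost multiplier (mass^(1-gamma) per day), `>= 0`.
#' @param gamma Cost exponent.
#'
#' @return An object of class `mass_params`.
#' @seealso [simulate_mass()], [relative_fecundity_rate()],
#'   [maintenance_fraction()]
#' @export
#' @examples
#' mass_params(a = 1, alpha = 2/3, b = 0.1, beta = 2/3, c = 0.3, gamma = 1)
mass_params <- function(a, alpha, b, beta, c, gamma) {
  vals <- base::c(a = a, alpha = alpha, b = b, beta = beta, c = c,
                  gamma = gamma)
  if (!all(is.finite(vals)))
    stop("all mass parameters must be finite numbers")
  if (a <= 0) stop("'a' must be > 0")
  if (b < 0) stop("'b' must be >= 0")
  if (c < 0) stop("'c' must be >= 0")
  structure(list(a = a, alpha = alpha, b = b, beta = beta, c = c,
                 gamma = gamma),
            class = "mass_params")
}

#' @export
print.mass_params <- function(x, ...) {
  cat("Body-mass model parameters\n")
  cat(sprintf("  acquisition : a = %g, alpha = %g\n", x$a, x$alpha))
  cat(sprintf("  gonadic     : b = %g, beta  = %g\n", x$b, x$beta))
  cat(sprintf("  non-growth  : c = %g, gamma = %g\n", x$c, x$gamma))
  invisible(x)
}

#' Mass--length power transformation
#'
#' The somatic mass `s` and body length `l` are linked by `s = h l^k`. For
#' Daphnia a cubic transformation (`k = 3`) is the usual choice.
#'
#' @param h Mass per length^k multiplier, `> 0`.
#' @param k Mass--length exponent, `> 0`; default 3 (cubic).
#'
#' @return An object of class `length_scale`.
#' @export
length_scale <- function(h, k = 3) {
  if (!is.finite(h) || h <= 0) stop("'h' must be a finite positive number")
  if (!is.finite(k) || k <= 0) stop("'k' must be a finite positive number")
  structure(list(h = h, k = k), class = "length_scale")
}

#' Body-length growth parameters
#'
#' Parameters of the reduced body-length equation
#' `dl = q (1 - r_t) l^lambda dt`. In terms of the body-mass model with
#' mass--length scale `(h, k)` and proportional maintenance (`gamma = alpha`),
#' `q = (h^(alpha - 1) / k) (a - c)` and `lambda = k (alpha - 1) + 1`.
#'
#' @param q Growth-rate scalar (length^(1-lambda) per day), `> 0`.
#' @param lambda Length-scale exponent (dimensionless); typically `< 1` for
#'   finite asymptotic growth, but any finite value is accepted.
#'
#' @return An object of class `growth_params`.
#' @seealso [simulate_length()], [lambda_from_alpha()]
#' @export
growth_params <- function(q, lambda) {
  if (!is.finite(q) || q <= 0) stop("'q' must be a finite positive number")
  if (!is.finite(lambda)) stop("'lambda' must be finite")
  structure(list(q = q, lambda = lambda), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Body-length growth parameters: q = %g, lambda = %g\n",
              x$q, x$lambda))
  invisible(x)
}

#' Time-varying reproduction-investment schedule
#'
#' Values of the instantaneous relative fecundity investment `r_t = dg/dm`
#' (the fraction of the total-mass increment allocated to gonadic growth) on
#' a time grid. `r` is 0 at birth and stays in `[0, 1)`. Between grid points
#' the schedule is interpreted linearly; beyond the last point it is held
#' constant.
#'
#' @param times Strictly increasing time grid in days, starting at 0.
#' @param r Values of `r_t` at `times`, each in `[0, 1)` with `r[1] == 0`.
#' @param r0_zero Enforce `r[1] == 0` (default `TRUE`, the experimental
#'   assumption that reproduction investment is zero at birth). Set to
#'   `FALSE` for schedules derived from the general body-mass model, where
#'   gonadic investment starts immediately.
#'
#' @return An object of class `allocation_schedule`.
#' @export
#' @examples
#' tt <- seq(0, 60, by = 0.5)
#' allocation_schedule(tt, 0.7 * (1 - exp(-tt / 8)))
allocation_schedule <- function(times, r, r0_zero = TRUE) {
  if (length(times) != length(r))
    stop("'times' and 'r' must have equal length")
  if (length(times) < 1L) stop("schedule must contain at least one point")
  if (!all(is.finite(times)) || !all(is.finite(r)))
    stop("schedule values must be finite")
  if (times[1] != 0) stop("schedule must start at time 0")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (r0_zero && abs(r[1]) > .Machine$double.eps)
    stop("r at time 0 must equal 0 (no reproduction investment at birth)")
  if (any(r < 0) || any(r >= 1)) stop("all r values must lie in [0, 1)")
  structure(list(times = as.numeric(times), r = as.numeric(r)),
            class = "allocation_schedule")
}

#' @export
print.allocation_schedule <- function(x, ...) {
  cat(sprintf(
    "Reproduction-investment schedule: %d knots on [0, %g] days, r in [%.3g, %.3g]\n",
    length(x$times), max(x$times), min(x$r), max(x$r)))
  invisible(x)
}

# r(t) evaluator: linear between knots, constant beyond the last knot.
schedule_fun <- function(schedule) {
  if (length(schedule$times) == 1L) {
    r0 <- schedule$r[1]
    return(function(t) rep(r0, length(t)))
  }
  stats::approxfun(schedule$times, schedule$r, method = "linear", rule = 2)
}

#' Convert between the mass exponent alpha and the length exponent lambda
#'
#' Under the power transformation `s = h l^k`, the body-mass acquisition
#' exponent `alpha` and the body-length exponent `lambda` are linked by
#' `lambda = k (alpha - 1) + 1`.
#'
#' @param alpha Acquisition exponent in the body-mass model.
#' @param lambda Length-scale exponent in the body-length model.
#' @param k Mass--length exponent, `> 0`; default 3.
#'
#' @return The converted exponent.
#' @export
#' @examples
#' lambda_from_alpha(2/3, 3)   # classical von Bertalanffy: lambda = 0
#' alpha_from_lambda(0.179, 3) # 0.726, close to 2/3
lambda_from_alpha <- function(alpha, k = 3) {
  if (!is.finite(alpha) || !is.finite(k)) stop("inputs must be finite")
  if (k <= 0) stop("'k' must be > 0")
  k * (alpha - 1) + 1
}

#' @rdname lambda_from_alpha
#' @export
alpha_from_lambda <- function(lambda, k = 3) {
  if (!is.finite(lambda) || !is.finite(k)) stop("inputs must be finite")
  if (k <= 0) stop("'k' must be > 0")
  1 + (lambda - 1) / k
}

#' Convert between somatic mass and body length
#'
#' Applies the power transformation `s = h l^k` (direction
#' `"length_to_mass"`) or its inverse `l = (s / h)^(1/k)`
#' (`"mass_to_length"`).
#'
#' @param scale A [length_scale()] object.
#' @param value Positive mass or length value(s).
#' @param direction Either `"length_to_mass"` or `"mass_to_length"`.
#'
#' @return The converted value(s).
#' @export
mass_length_convert <- function(scale, value,
                                direction = c("length_to_mass",
                                              "mass_to_length")) {
  direction <- match.arg(direction)
  stopifnot(inherits(scale, "length_scale"))
  if (any(!is.finite(value)) || any(value <= 0))
    stop("'value' must be positive and finite")
  if (direction == "length_to_mass") scale$h * value^scale$k
  else (value / scale$h)^(1 / scale$k)
}

#' Instantaneous relative fecundity investment implied by the mass model
#'
#' Computes `r_t = dg/dm = b s^(beta - alpha) / (a (1 - p))` with maintenance
#' fraction `p = (c/a) s^(gamma - alpha)`, the share of the total-mass
#' increment that goes to gonadic growth at somatic mass `s`.
#'
#' @param params A [mass_params()] object.
#' @param s Somatic mass (positive; vectorised).
#'
#' @return `r` value(s) in `[0, 1)`. Values outside that range indicate an
#'   inadmissible parameter set and raise an error rather than being
#'   returned.
#' @export
relative_fecundity_rate <- function(params, s) {
  stopifnot(inherits(params, "mass_params"))
  if (any(!is.finite(s)) || any(s <= 0)) stop("'s' must be positive")
  p <- maintenance_fraction(params, s)
  denom <- params$a * (1 - p)
  if (any(denom <= 0))
    stop("total-mass increment dm <= 0 at this somatic mass: ",
         "a s^alpha must exceed c s^gamma")
  r <- params$b * s^(params$beta - params$alpha) / denom
  if (any(r >= 1))
    stop("parameters imply r_t >= 1 (all acquired energy to reproduction); ",
         "the model requires a s^alpha - c s^gamma > b s^beta")
  r
}

#' Maintenance fraction of acquired energy
#'
#' Computes `p_t = (c/a) s^(gamma - alpha)`, the fraction of acquired energy
#' spent on non-body-growth components. When `gamma = alpha` (maintenance
#' proportional to intake) this is the constant `c/a`.
#'
#' @inheritParams relative_fecundity_rate
#' @return `p` value(s), `>= 0`.
#' @export
maintenance_fraction <- function(params, s) {
  stopifnot(inherits(params, "mass_params"))
  if (any(!is.finite(s)) || any(s <= 0)) stop("'s' must be positive")
  if (params$a == 0) stop("'a' must be nonzero")
  (params$c / params$a) * s^(params$gamma - params$alpha)
}

# Grid of spacing <= step from 0 to t_end, always containing t_end.
integration_grid <- function(t_end, step) {
  n <- ceiling(t_end / step)
  seq(0, t_end, length.out = n + 1L)
}

#' Forward-simulate the body-length growth equation
#'
#' Integrates `dl = q (1 - r_t) l^lambda dt` with a fixed-step fourth-order
#' Runge--Kutta scheme. The reproduction-investment schedule is linearly
#' interpolated between its knots and held constant beyond the last knot.
#'
#' @param params A [growth_params()] object.
#' @param schedule An [allocation_schedule()] object (or `NULL` for
#'   `r == 0` throughout).
#' @param l0 Birth length (mm), `> 0`.
#' @param t_end End of the simulation (days since birth).
#' @param step Integration step in days (default 0.05); the realised grid
#'   spacing never exceeds `step`.
#'
#' @return An object of class `length_trajectory`: a list with `times` and
#'   `lengths` (mm).
#' @export
#' @examples
#' sched <- allocation_schedule(c(0, 30), c(0, 0.6))
#' traj <- simulate_length(growth_params(0.169, 0.179), sched, 0.8, 60)
#' tail(traj$lengths, 1)
simulate_length <- function(params, schedule, l0, t_end, step = 0.05) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.finite(l0) || l0 <= 0) stop("'l0' must be positive")
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be positive")
  if (is.null(schedule)) {
    rfun <- function(t) rep(0, length(t))
  } else {
    stopifnot(inherits(schedule, "allocation_schedule"))
    rfun <- schedule_fun(schedule)
  }
  times <- integration_grid(t_end, step)
  if (any(rfun(times) >= 1))
    stop("schedule implies r_t >= 1 on the integration grid; ",
         "negative growth is not admitted by the model")
  q <- params$q
  lambda <- params$lambda
  deriv <- function(t, y, parms) list(q * (1 - rfun(t)) * y[1]^lambda)
  sol <- deSolve::ode(y = base::c(l = l0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  structure(list(times = as.numeric(sol[, "time"]),
                 lengths = as.numeric(sol[, "l"])),
            class = "length_trajectory")
}

#' Forward-simulate the somatic/gonadic body-mass system
#'
#' Integrates `ds = (a s^alpha - c s^gamma - b s^beta) dt` and
#' `dg = b s^beta dt` with fixed-step fourth-order Runge--Kutta. The gonadic
#' mass is zero at birth and is reset to zero immediately *after* each brood
#' time, so the value stored at a brood time is the gonadic investment
#' released in that brood.
#'
#' @param params A [mass_params()] object.
#' @param s0 Somatic mass at birth, `> 0`, with positive initial growth.
#' @param brood_times Times of neonate release (days, within `[0, t_end]`);
#'   may be empty.
#' @param t_end End of the simulation (days).
#' @param step Integration step in days (default 0.05).
#'
#' @return An object of class `mass_trajectory`: a list with `times`,
#'   `somatic`, `gonadic`, `total` and `brood_times`.
#' @export
simulate_mass <- function(params, s0, brood_times = numeric(), t_end,
                          step = 0.05) {
  stopifnot(inherits(params, "mass_params"))
  if (!is.finite(s0) || s0 <= 0) stop("'s0' must be positive")
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be positive")
  ds0 <- params$a * s0^params$alpha - params$c * s0^params$gamma -
    params$b * s0^params$beta
  if (ds0 <= 0)
    stop("ds/dt <= 0 at s0: the model does not admit shrinkage")
  brood_times <- sort(unique(as.numeric(brood_times)))
  if (length(brood_times) &&
      (any(brood_times < 0) || any(brood_times > t_end)))
    stop("'brood_times' must lie within [0, t_end]")

  deriv <- function(t, y, parms) {
    s <- y[1]
    dg <- params$b * s^params$beta
    ds <- params$a * s^params$alpha - params$c * s^params$gamma - dg
    list(base::c(ds, dg))
  }

  # integrate segment-wise between brood times, resetting g after each
  bounds <- unique(base::c(0, brood_times[brood_times > 0 &
                                            brood_times < t_end], t_end))
  times <- numeric(0); s_out <- numeric(0); g_out <- numeric(0)
  state <- base::c(s = s0, g = 0)
  for (j in seq_len(length(bounds) - 1L)) {
    seg <- bounds[j] + integration_grid(bounds[j + 1L] - bounds[j], step)
    sol <- deSolve::ode(y = state, times = seg, func = deriv, parms = NULL,
                        method = "rk4")
    keep <- if (j == 1L) seq_len(nrow(sol)) else -1L
    times <- base::c(times, sol[keep, "time"])
    s_out <- base::c(s_out, sol[keep, "s"])
    g_out <- base::c(g_out, sol[keep, "g"])
    state <- base::c(s = unname(sol[nrow(sol), "s"]), g = 0)  # brood reset
  }
  structure(list(times = as.numeric(times), somatic = as.numeric(s_out),
                 gonadic = as.numeric(g_out),
                 total = as.numeric(s_out + g_out),
                 brood_times = brood_times),
            class = "mass_trajectory")
}
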