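# Gradient-matching estimation of (q per scenario, shared lambda, r_t per
# scenario, sigma) from uneven-time length observations.
#
# Estimation design, in brief: each individual's trajectory is smoothed by
# local quadratic loess onto a regular dt grid. Because the fitted level and
# its finite-difference derivative share the same observations, their errors
# are positively correlated and a naive profile over lambda is badly biased;
# the fit therefore smooths two interleaved halves of each trajectory and
# pairs the level of one half with the derivative of the other (both
# orientations pooled). Rows are weighted by trapezium quadrature weights
# divided by the squared fitted length, the inverse-variance weighting under
# multiplicative measurement error; grid times before an individual's second
# observation (its first brood) contain no gradient information for that
# individual and are dropped. The growth scalar q = f(0) is anchored across
# the unobserved birth-to-maturation gap by a saturating-exponential fit to
# the per-time coefficient curve f_t = q (1 - r_t).

#' Trapezium quadrature weights on a regular grid
#'
#' Weights for approximating an integral over the grid span: `dt/2` at both
#' ends, `dt` at interior points. The weights sum to the span of the grid.
#'
#' @param grid Regularly spaced, increasing time grid with at least 2 points.
#' @return Numeric vector of weights, one per grid point.
#' @export
#' @examples
#' trapezium_weights(c(0, 0.5, 1)) # 0.25 0.50 0.25
trapezium_weights <- function(grid) {
  n <- length(grid)
  if (n < 2L) stop("trapezium weights need at least 2 grid points")
  d <- diff(grid)
  if (any(d <= 0) || max(d) - min(d) > 1e-8 * max(d))
    stop("'grid' must be increasing and uniformly spaced")
  dt <- mean(d)
  base::c(dt / 2, rep(dt, n - 2L), dt / 2)
}

# loess prediction on a grid with a per-individual span floor and a widening
# retry ladder; NULL when every candidate span is degenerate
loess_on_grid <- function(times, lengths, grid, span, floor_pts = 7) {
  span_use <- max(span, min(1, floor_pts / length(times)))
  for (sp in unique(pmin(base::c(span_use, span_use + 0.2, span_use + 0.4, 1), 1))) {
    fit <- tryCatch(
      stats::loess(lengths ~ times, span = sp, degree = 2,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit)) next
    out <- tryCatch(stats::predict(fit, newdata = data.frame(times = grid)),
                    error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out)) && all(out > 0))
      return(list(fitted = as.numeric(out), model = fit, span = sp))
  }
  NULL
}

#' Smooth one individual's length trajectory onto a regular grid
#'
#' Fits a local quadratic loess (tricube weights) to the uneven-time length
#' observations and evaluates the fitted curve and its time derivative on a
#' regular grid of spacing `grid_step` over `[0, t_max]`, together with
#' trapezium quadrature weights. The derivative is taken by central finite
#' differences of the fitted curve on the grid (one-sided at the ends); set
#' `deriv_method = "local_slope"` for the slope of the local polynomial
#' (central differences of the loess prediction at a much finer spacing).
#' The span is floored at `7 / n` observations so every local window
#' supports a quadratic, and widened stepwise if the fit is degenerate.
#'
#' @param times Strictly increasing observation times (days), starting at
#'   birth.
#' @param lengths Observed body lengths (mm) at `times`.
#' @param grid_step Grid spacing in days (default 0.5).
#' @param span Loess span (default 0.5).
#' @param deriv_method `"finite_diff"` (default) or `"local_slope"`.
#'
#' @return An object of class `smoothed_trajectory` with elements `times`
#'   (the grid), `fitted`, `deriv`, `weights` and `residuals`, or `NULL`
#'   (with a warning) when fewer than 5 observations are available.
#' @export
smooth_trajectory <- function(times, lengths, grid_step = 0.5, span = 0.5,
                              deriv_method = c("finite_diff", "local_slope")) {
  deriv_method <- match.arg(deriv_method)
  if (length(times) != length(lengths))
    stop("'times' and 'lengths' must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (length(times) < 5L) {
    warning(sprintf(
      "trajectory with %d observation(s) excluded: at least 5 are needed for smoothing",
      length(times)))
    return(NULL)
  }
  t_max <- times[length(times)]
  grid <- seq(0, floor(t_max / grid_step) * grid_step, by = grid_step)
  if (length(grid) < 2L) {
    warning("trajectory shorter than one grid step excluded")
    return(NULL)
  }
  sm <- loess_on_grid(times, lengths, grid, span)
  if (is.null(sm))
    stop("loess produced nonpositive fitted lengths at every candidate span")
  if (deriv_method == "finite_diff") {
    dl <- finite_diff(grid, sm$fitted)
  } else {
    eps <- grid_step / 100
    tq <- pmin(pmax(grid, eps), t_max - eps)
    up <- stats::predict(sm$model, newdata = data.frame(times = tq + eps))
    dn <- stats::predict(sm$model, newdata = data.frame(times = tq - eps))
    dl <- as.numeric(up - dn) / (2 * eps)
  }
  structure(list(times = grid, fitted = sm$fitted, deriv = dl,
                 weights = trapezium_weights(grid),
                 residuals = lengths -
                   as.numeric(stats::predict(sm$model,
                                             newdata = data.frame(times = times)))),
            class = "smoothed_trajectory")
}

# central differences with one-sided ends on a grid
finite_diff <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L)
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

# Cross-fit smoothing of one individual: the observations are split into two
# interleaved halves (both keep the first and last point so the grid stays
# covered) and each half is loess-smoothed separately. Individuals with
# fewer than 8 observations fall back to a single full-data fit for both
# halves. Returns NULL (caller warns/excludes) for degenerate trajectories.
crossfit_trajectory <- function(times, lengths, grid_step = 0.5,
                                span = 0.5) {
  n <- length(times)
  if (n < 5L) return(NULL)
  t_max <- times[n]
  grid <- seq(0, floor(t_max / grid_step) * grid_step, by = grid_step)
  if (length(grid) < 2L) return(NULL)
  if (n >= 8L) {
    inner <- seq_len(n)[-base::c(1L, n)]
    ia <- sort(base::c(1L, n, inner[seq(1, length(inner), by = 2)]))
    ib <- sort(base::c(1L, n, inner[seq(2, length(inner), by = 2)]))
    sa <- loess_on_grid(times[ia], lengths[ia], grid, span, floor_pts = 5)
    sb <- loess_on_grid(times[ib], lengths[ib], grid, span, floor_pts = 5)
  } else {
    sa <- sb <- loess_on_grid(times, lengths, grid, span, floor_pts = 5)
  }
  if (is.null(sa) || is.null(sb)) return(NULL)
  # relative measurement variance, roughly: residuals of each half's inner
  # observations against the other half's fit (mildly inflated by the
  # prediction error, hence the shrinkage factor)
  cross_res <- function(model, sel) {
    pr <- tryCatch(stats::predict(model,
                                  newdata = data.frame(times = times[sel])),
                   error = function(e) rep(NA_real_, length(sel)))
    (lengths[sel] - pr) / lengths[sel]
  }
  rr <- base::c(cross_res(sa$model, setdiff(seq_len(n), base::c(1L, n))[
    seq(2, n - 2, by = 2)]),
    cross_res(sb$model, setdiff(seq_len(n), base::c(1L, n))[
      seq(1, n - 2, by = 2)]))
  rr <- rr[is.finite(rr)]
  sig2_rel <- if (length(rr) >= 4) 0.8 * mean(rr^2) else NA_real_
  list(times = grid, la = sa$fitted, lb = sb$fitted,
       dla = finite_diff(grid, sa$fitted), dlb = finite_diff(grid, sb$fitted),
       weights = trapezium_weights(grid),
       t2 = times[2], death = t_max,
       l0_obs = lengths[1], l2_obs = lengths[2],
       z_gap = (lengths[2] - lengths[1]) / (times[2] - times[1]),
       sig2_rel = sig2_rel)
}

# Cross-fit smooth every individual; excluded individuals dropped with one
# pooled warning.
prepare_trajectories <- function(dataset, grid_step = 0.5, span = 0.5) {
  stopifnot(inherits(dataset, "growth_dataset"))
  ids <- unique(dataset$individual_id)
  out <- vector("list", length(ids))
  excluded <- character(0)
  for (j in seq_along(ids)) {
    rows <- dataset[dataset$individual_id == ids[j], , drop = FALSE]
    cf <- if (nrow(rows) >= 5L)
      crossfit_trajectory(rows$time_days, rows$length_mm,
                          grid_step = grid_step, span = span) else NULL
    if (is.null(cf)) {
      excluded <- base::c(excluded, ids[j])
    } else {
      cf$id <- ids[j]
      cf$scenario <- rows$scenario[1]
      out[[j]] <- cf
    }
  }
  if (length(excluded))
    warning(sprintf(
      "%d individual(s) excluded (fewer than 5 observations or degenerate smooth): %s",
      length(excluded), paste(utils::head(excluded, 5), collapse = ", ")))
  Filter(Negate(is.null), out)
}

# Pool one scenario's cross-fit trajectories into flat vectors keyed by grid
# index. Both pairings (level A / derivative B and level B / derivative A)
# contribute; grid times before the individual's second observation are
# dropped (no gradient information there). Weights are trapezium weights
# over 1/l^2 (inverse variance under multiplicative noise), halved so the
# two orientations jointly carry each grid point's quadrature weight.
pool_crossfit <- function(prepped, grid_step) {
  t_idx <- integer(0); w <- numeric(0); l <- numeric(0); dl <- numeric(0)
  w_plain <- numeric(0); ind <- integer(0)
  for (j in seq_along(prepped)) {
    s <- prepped[[j]]
    keep <- s$times >= s$t2
    if (!any(keep)) next
    ti <- as.integer(round(s$times[keep] / grid_step))
    wt <- s$weights[keep] / 2
    t_idx <- base::c(t_idx, ti, ti)
    w <- base::c(w, wt / s$la[keep]^2, wt / s$lb[keep]^2)
    l <- base::c(l, s$la[keep], s$lb[keep])
    dl <- base::c(dl, s$dlb[keep], s$dla[keep])
    w_plain <- base::c(w_plain, wt, wt)
    ind <- base::c(ind, rep(j, 2 * sum(keep)))
  }
  if (!length(t_idx)) stop("no usable grid rows in scenario pool")
  # risk set: individuals contributing at each grid cell (each appears twice)
  counts <- rowsum(rep(0.5, length(t_idx)), t_idx)[, 1]
  list(t_idx = t_idx, w = w, l = l, dl = dl, w_plain = w_plain,
       counts = counts, grid_step = grid_step,
       n_ind = length(unique(ind)))
}

# weighted per-cell WLS solution and SSE on a pooled set of rows
pool_wls <- function(pool, lambda, weights = pool$w) {
  ll <- pool$l^lambda
  a <- weights * ll * pool$dl
  b <- weights * ll * ll
  fac <- factor(pool$t_idx)
  num <- rowsum(a, fac)[, 1]
  den <- rowsum(b, fac)[, 1]
  f <- num / den
  sse <- max(sum(weights * pool$dl^2) - sum(num^2 / den), 0)
  list(times = as.numeric(names(num)) * pool$grid_step, f = unname(f),
       den = unname(den), sse = sse, sum_w = sum(weights),
       counts = unname(pool$counts[names(num)]))
}

pool_sse <- function(pool, lambda) {
  ll <- pool$l^lambda
  a <- pool$w * ll * pool$dl
  b <- pool$w * ll * ll
  fac <- factor(pool$t_idx)
  num <- rowsum(a, fac)[, 1]
  den <- rowsum(b, fac)[, 1]
  max(sum(pool$w * pool$dl^2) - sum(num^2 / den), 0)
}

#' Per-grid-time weighted least-squares coefficient
#'
#' For a fixed length exponent `lambda`, solves at every grid time `t` the
#' weighted least-squares problem for `f_t := q (1 - r_t)` across the
#' individuals alive at `t`:
#' `f_t = sum_i w_it l_it^lambda (dl_it/dt) / sum_i w_it l_it^(2 lambda)`,
#' and returns the raw coefficient curve with the weighted sum of squared
#' gradient errors. Grid times with no surviving individual are truncated,
#' not imputed.
#'
#' @param smoothed List of [smooth_trajectory()] results for one scenario.
#' @param lambda Length-scale exponent at which to evaluate.
#' @param grid_step Grid spacing used when smoothing (default 0.5).
#'
#' @return A list with `times`, `f` (the raw `q (1 - r_t)` curve), `sse`
#'   (weighted sum of squares) and `sum_w` (total weight).
#' @export
pergrid_coefficient <- function(smoothed, lambda, grid_step = 0.5) {
  if (!length(smoothed)) stop("no smoothed trajectories supplied")
  if (inherits(smoothed, "smoothed_trajectory")) smoothed <- list(smoothed)
  t_idx <- unlist(lapply(smoothed, function(s) round(s$times / grid_step)))
  pool <- list(t_idx = as.integer(t_idx),
               w = unlist(lapply(smoothed, `[[`, "weights")),
               l = unlist(lapply(smoothed, `[[`, "fitted")),
               dl = unlist(lapply(smoothed, `[[`, "deriv")),
               counts = rowsum(rep(1, length(t_idx)), t_idx)[, 1],
               grid_step = grid_step)
  res <- pool_wls(pool, lambda, weights = pool$w)
  list(times = res$times, f = res$f, sse = res$sse, sum_w = res$sum_w)
}

# Saturating-exponential anchor f(t) = f_inf + (f_0 - f_inf) exp(-t/theta),
# fitted jointly to (i) the supported part of the raw coefficient curve and
# (ii) each individual's observed birth-to-first-brood increment, whose
# expectation under the family is (1/t2) int_0^t2 f(u) l(u)^lambda du. The
# increments are the only data inside the pre-reproductive gap and pin down
# f near birth, where the grid curve has no direct support. For a fixed
# decay timescale theta the model is linear in (f_inf, f_0 - f_inf), so the
# fit profiles a 2-parameter weighted least squares over theta.
anchor_fit <- function(tt, f, den, s2_pool, gaps) {
  w_cells <- den / max(s2_pool, 1e-12)
  have_gaps <- length(gaps$z) > 0
  solve_at <- function(theta) {
    x1 <- base::c(rep(1, length(tt)), if (have_gaps) gaps$I0)
    x2 <- base::c(exp(-tt / theta),
                  if (have_gaps) vapply(seq_along(gaps$z), function(i)
                    sum(gaps$tw[[i]] * exp(-gaps$u[[i]] / theta) *
                          gaps$llam[[i]]) / gaps$t2[i], numeric(1)))
    y <- base::c(f, gaps$z)
    w <- base::c(w_cells, if (have_gaps) 1 / gaps$var_z)
    fit <- stats::lm.wfit(cbind(x1, x2), y, w)
    cf <- fit$coefficients
    if (!all(is.finite(cf)) || cf[2] < 0 || cf[1] < 0) {
      # degenerate direction: flat f (no early decay detectable)
      a <- sum(w * y * x1) / sum(w * x1^2)
      cf <- base::c(max(a, 1e-8), 0)
      res <- y - cf[1] * x1
      return(list(coef = cf, sse = sum(w * res^2)))
    }
    list(coef = cf, sse = sum(w * fit$residuals^2))
  }
  opt <- tryCatch(
    stats::optimize(function(th) solve_at(th)$sse, interval = base::c(0.5, 80)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  cf <- solve_at(opt$minimum)$coef
  list(f0 = cf[1] + cf[2], finf = cf[1], theta = opt$minimum,
       predict = function(t) cf[1] + cf[2] * exp(-t / opt$minimum))
}

# gap summaries for the anchor: per individual, the observed mean growth
# rate over [0, t2] and the quadrature pieces of int l^lambda over the gap
gap_data <- function(prepped_sc, lambda, sig2_rel) {
  z <- numeric(0); var_z <- numeric(0); t2 <- numeric(0)
  I0 <- numeric(0); u_l <- list(); tw_l <- list(); llam_l <- list()
  for (s in prepped_sc) {
    if (!is.finite(s$z_gap) || s$t2 <= 0) next
    lev <- (s$la + s$lb) / 2
    u <- base::c(s$times[s$times < s$t2], s$t2)
    if (length(u) < 2L) u <- base::c(0, s$t2)
    lu <- stats::approx(s$times, lev, xout = u, rule = 2)$y
    du <- diff(u)
    tw <- base::c(du / 2, 0) + base::c(0, du / 2)
    k <- length(z) + 1L
    z[k] <- s$z_gap
    t2[k] <- s$t2
    var_z[k] <- sig2_rel * (s$l0_obs^2 + s$l2_obs^2) / s$t2^2
    llam_l[[k]] <- lu^lambda
    u_l[[k]] <- u
    tw_l[[k]] <- tw
    I0[k] <- sum(tw * lu^lambda) / s$t2
  }
  list(z = z, var_z = pmax(var_z, 1e-12), t2 = t2, I0 = I0,
       u = u_l, tw = tw_l, llam = llam_l)
}

#' Fit the growth model by profile least squares on the gradient
#'
#' Estimates a shared length exponent `lambda`, a per-scenario growth scalar
#' `q`, a per-scenario time-varying reproduction-investment curve `r_t` and
#' a residual gradient scale `sigma` from uneven-time length records. Each
#' individual's trajectory is loess-smoothed onto a regular grid (two
#' interleaved observation halves, so fitted levels and derivatives carry
#' independent errors); for each candidate `lambda` the per-time coefficient
#' `f_t = q (1 - r_t)` has a closed-form weighted least-squares solution and
#' the profiled sum of squares is minimised over the `lambda` grid (with
#' quadratic refinement around the grid minimum; ties resolved to the
#' smallest `lambda`). The raw `f_t` curve is then smoothed over time by
#' loess, `q` is anchored at birth (where `r_0 = 0`) by a
#' saturating-exponential fit that carries `f_t` across the unobserved
#' birth-to-maturation gap, and `r_t = 1 - f_t / q` clipped to `[0, 1)`.
#'
#' @param dataset A [growth_dataset()].
#' @param lambda_grid Ordered grid of candidate exponents (default
#'   `seq(0, 0.6, by = 0.01)`); at least 3 points.
#' @param span Loess span for trajectory smoothing (default 0.35; floored
#'   at 5 observations per window in the cross-fit halves).
#' @param grid_step Time-grid spacing in days (default 0.5).
#' @param r_span Loess span for the second-stage smoothing of `f_t` over
#'   time (default 0.5).
#' @param min_risk Minimum number of individuals that must contribute to a
#'   grid time for it to enter the reported `r_t` support; default
#'   `max(3, 5%)` of the scenario cohort.
#'
#' @return An object of class `growth_fit` with elements `lambda_hat`,
#'   `q_hat` (named by scenario), `r_hat` (named list of
#'   [allocation_schedule()]), `theta_hat` (anchor timescale per scenario),
#'   `sigma_hat`, `sse`, `profile` (the `lambda`/SSE profile), `f_raw`
#'   (per-scenario raw coefficient curves), `scenario_info` (birth length
#'   and time span per scenario) and `options`.
#' @export
#' @examples
#' \donttest{
#' truth <- scenario_truth("constant_rearing")
#' pop <- generate_population(truth, n_individuals = 40, seed = 1)
#' fit <- profile_fit(pop, lambda_grid = seq(0, 0.6, by = 0.05))
#' fit$lambda_hat
#' fit$q_hat
#' }
profile_fit <- function(dataset, lambda_grid = seq(0, 0.6, by = 0.01),
                        span = 0.35, grid_step = 0.5, r_span = 0.5,
                        min_risk = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  check_lambda_grid(lambda_grid)
  prepped <- prepare_trajectories(dataset, grid_step = grid_step,
                                  span = span)
  if (!length(prepped)) stop("no usable individuals after exclusion")
  fit <- fit_prepped(prepped, lambda_grid = lambda_grid,
                     grid_step = grid_step, r_span = r_span,
                     min_risk = min_risk)
  fit$scenario_info <- scenario_info(dataset, names(fit$q_hat))
  fit$options <- list(lambda_grid = lambda_grid, span = span,
                      grid_step = grid_step, r_span = r_span)
  fit
}

check_lambda_grid <- function(lambda_grid) {
  if (length(lambda_grid) < 3L)
    stop("'lambda_grid' must contain at least 3 points")
  if (is.unsorted(lambda_grid, strictly = TRUE))
    stop("'lambda_grid' must be strictly increasing")
  invisible(lambda_grid)
}

scenario_info <- function(dataset, scenarios) {
  out <- lapply(scenarios, function(sc) {
    rows <- dataset[dataset$scenario == sc, , drop = FALSE]
    births <- rows$length_mm[rows$time_days == 0]
    list(l0 = mean(births), t_max = max(rows$time_days),
         n = length(unique(rows$individual_id)))
  })
  names(out) <- scenarios
  out
}

# Core estimator operating on cross-fit trajectories (reused by the
# bootstrap so each individual is smoothed exactly once).
fit_prepped <- function(prepped, lambda_grid, grid_step = 0.5,
                        r_span = 0.5, min_risk = NULL, blend_days = 5) {
  scen <- vapply(prepped, `[[`, character(1), "scenario")
  pools <- lapply(split(prepped, scen), pool_crossfit,
                  grid_step = grid_step)

  sse_at <- function(lambda)
    sum(vapply(pools, pool_sse, numeric(1), lambda = lambda))
  profile <- vapply(lambda_grid, sse_at, numeric(1))

  i <- which(profile == min(profile))[1]  # ties -> smallest lambda
  lambda_hat <- lambda_grid[i]
  if (i == 1L || i == length(lambda_grid)) {
    warning("profiled minimum at the boundary of 'lambda_grid'; ",
            "widen lambda_grid")
  } else {
    # quadratic refinement through the three points around the minimum
    x <- lambda_grid[(i - 1):(i + 1)]
    y <- profile[(i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    aq <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
             x[1] * (y[3] - y[2])) / denom
    bq <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
             x[1]^2 * (y[2] - y[3])) / denom
    if (is.finite(aq) && aq > 0) {
      cand <- -bq / (2 * aq)
      if (cand > x[1] && cand < x[3] && sse_at(cand) <= profile[i])
        lambda_hat <- cand
    }
  }

  by_scen <- split(prepped, scen)
  q_hat <- numeric(0)
  theta_hat <- numeric(0)
  r_hat <- list()
  f_raw <- list()
  total_sse_plain <- 0
  total_w_plain <- 0
  for (sc in names(pools)) {
    pool <- pools[[sc]]
    pg <- pool_wls(pool, lambda_hat)
    plain <- pool_wls(pool, lambda_hat, weights = pool$w_plain)
    total_sse_plain <- total_sse_plain + plain$sse
    total_w_plain <- total_w_plain + plain$sum_w

    need <- if (is.null(min_risk))
      max(3, ceiling(0.05 * pool$n_ind)) else min_risk
    supported <- pg$counts >= need & is.finite(pg$f)
    if (sum(supported) < 5L)
      stop("scenario '", sc, "' has too few supported grid times")
    tt <- pg$times[supported]
    ft <- pg$f[supported]
    wt <- pg$den[supported]

    # residual variance per unit weight of the pooled gradient WLS, and the
    # relative measurement variance, to calibrate the anchor's two blocks
    n_cells <- length(pg$times)
    s2_pool <- pg$sse / max(length(pool$t_idx) - n_cells, 1)
    sig2_sc <- stats::median(vapply(by_scen[[sc]], `[[`, numeric(1),
                                    "sig2_rel"), na.rm = TRUE)
    if (!is.finite(sig2_sc) || sig2_sc <= 0) sig2_sc <- 1e-4
    gaps <- gap_data(by_scen[[sc]], lambda_hat, sig2_sc)
    # grid cells within ~one smoothing window of the support start sit on
    # the boundary of the pre-reproductive gap and carry its bias; the
    # anchor uses the cells beyond that zone plus the (unbiased) gap
    # increments, which jointly identify (f_inf, f_0, theta)
    past_edge <- tt >= min(tt) + 10
    use <- if (sum(past_edge) >= 5L) past_edge else rep(TRUE, length(tt))
    anchor <- anchor_fit(tt[use], ft[use], wt[use], s2_pool, gaps)
    sm <- stats::loess(ft ~ tt, weights = wt, span = r_span, degree = 2,
                       control = stats::loess.control(surface = "direct"))
    if (is.null(anchor)) {
      warning("saturating-exponential anchor failed for scenario '", sc,
              "'; falling back to loess extrapolation at birth")
      q_sc <- as.numeric(stats::predict(sm, newdata = data.frame(tt = 0)))
      theta_sc <- NA_real_
      f_report_fun <- function(t)
        as.numeric(stats::predict(sm, newdata = data.frame(tt = t)))
    } else {
      q_sc <- anchor$f0
      theta_sc <- anchor$theta
      t_lo <- min(tt)
      f_loess <- function(t)
        as.numeric(stats::predict(sm, newdata = data.frame(tt = t)))
      f_report_fun <- function(t) {
        wgt <- pmin(pmax((t - t_lo) / blend_days, 0), 1)
        (1 - wgt) * anchor$predict(t) + wgt * f_loess(pmax(t, t_lo))
      }
    }
    if (!is.finite(q_sc) || q_sc <= 0)
      stop("estimated q <= 0 for scenario '", sc,
           "'; the gradient signal near birth is not positive")

    r_times <- seq(0, max(tt), by = grid_step)
    f_rep <- f_report_fun(r_times)
    r <- pmin(pmax(1 - f_rep / q_sc, 0), 1 - 1e-9)
    r[1] <- 0
    q_hat[sc] <- unname(q_sc)
    theta_hat[sc] <- unname(theta_sc)
    r_hat[[sc]] <- allocation_schedule(r_times, r)
    f_raw[[sc]] <- data.frame(time_days = tt, f_raw = ft,
                              risk_set = pg$counts[supported])
  }

  structure(list(lambda_hat = lambda_hat, q_hat = q_hat, r_hat = r_hat,
                 theta_hat = theta_hat,
                 sigma_hat = sqrt(total_sse_plain / total_w_plain),
                 sse = sse_at(lambda_hat),
                 profile = data.frame(lambda = lambda_grid, sse = profile),
                 f_raw = f_raw, prepped = prepped),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Gradient-matching growth fit\n")
  cat(sprintf("  shared lambda: %.4f\n", x$lambda_hat))
  for (sc in names(x$q_hat)) {
    line <- sprintf("  %-22s q = %.4f", sc, x$q_hat[[sc]])
    if (!is.null(x$ci) && sc %in% rownames(x$ci$q))
      line <- paste0(line, sprintf("  (%.4f, %.4f)",
                                   x$ci$q[sc, 1], x$ci$q[sc, 2]))
    cat(line, "\n")
  }
  cat(sprintf("  sigma = %.4g, objective = %.4g\n", x$sigma_hat, x$sse))
  invisible(x)
}

#' Bootstrap confidence intervals for the growth fit
#'
#' Nonparametric bootstrap resampling individuals with replacement within
#' each scenario. Each replicate refits the profile least squares (reusing
#' the per-individual smoothing) and recomputes the lifetime summaries
#' (mean lifespan and scaled cumulative neonate count at the mean lifespan).
#' Percentile intervals are returned for `lambda`, each scenario's `q`,
#' `tau` and `N_tau`.
#'
#' @param dataset A [growth_dataset()].
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed; the same seed reproduces the intervals exactly.
#' @param level Interval level (default 0.95).
#' @param lambda_grid,span,grid_step,r_span Passed to [profile_fit()].
#'
#' @return The full-data `growth_fit` with an added `ci` element: a list of
#'   matrices (`lambda`, `q`, `tau`, `n_tau`) with columns `lower`/`upper`,
#'   plus `B_used`, the number of replicates that fitted successfully.
#' @export
bootstrap_ci <- function(dataset, B = 200, seed, level = 0.95,
                         lambda_grid = seq(0, 0.6, by = 0.01), span = 0.35,
                         grid_step = 0.5, r_span = 0.5) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (missing(seed)) stop("'seed' is required for the bootstrap")
  if (B < 2) stop("'B' must be at least 2")

  fit <- profile_fit(dataset, lambda_grid = lambda_grid, span = span,
                     grid_step = grid_step, r_span = r_span)
  scenarios <- names(fit$q_hat)
  base_summary <- lifetime_summary(fit, dataset)

  prepped <- fit$prepped
  scen_of <- vapply(prepped, `[[`, character(1), "scenario")
  by_scen <- split(seq_along(prepped), scen_of)
  rows_by_id <- split(seq_len(nrow(dataset)), dataset$individual_id)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  draws <- list(lambda = numeric(0),
                q = matrix(numeric(0), ncol = length(scenarios),
                           dimnames = list(NULL, scenarios)),
                tau = matrix(numeric(0), ncol = length(scenarios),
                             dimnames = list(NULL, scenarios)),
                n_tau = matrix(numeric(0), ncol = length(scenarios),
                               dimnames = list(NULL, scenarios)))
  dropped <- 0L
  for (b in seq_len(B)) {
    picks <- lapply(by_scen, function(idx)
      idx[sample.int(length(idx), length(idx), replace = TRUE)])
    res <- tryCatch(withCallingHandlers({
      represampled <- prepped[unlist(picks)]
      # relabel so duplicated draws count as distinct individuals
      ids <- vapply(represampled, `[[`, character(1), "id")
      new_ids <- paste0(ids, "#", seq_along(ids))
      for (j in seq_along(represampled)) represampled[[j]]$id <- new_ids[j]
      bfit <- fit_prepped(represampled, lambda_grid = lambda_grid,
                          grid_step = grid_step, r_span = r_span)
      # rebuild the matching dataset for lifetime summaries
      blocks <- lapply(seq_along(ids), function(j) {
        rows <- dataset[rows_by_id[[ids[j]]], , drop = FALSE]
        rows$individual_id <- new_ids[j]
        rows
      })
      bdata <- growth_dataset(do.call(rbind, blocks))
      bfit$scenario_info <- scenario_info(bdata, names(bfit$q_hat))
      bsum <- lifetime_summary(bfit, bdata)
      list(lambda = bfit$lambda_hat,
           q = bfit$q_hat[scenarios],
           tau = stats::setNames(bsum$tau_hat, bsum$scenario)[scenarios],
           n_tau = stats::setNames(bsum$n_tau, bsum$scenario)[scenarios])
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    draws$lambda <- base::c(draws$lambda, res$lambda)
    draws$q <- rbind(draws$q, res$q)
    draws$tau <- rbind(draws$tau, res$tau)
    draws$n_tau <- rbind(draws$n_tau, res$n_tau)
  }
  if (dropped > 0.2 * B)
    stop(sprintf("%d of %d bootstrap replicates failed to fit", dropped, B))

  probs <- base::c((1 - level) / 2, 1 - (1 - level) / 2)
  qmat <- function(m) t(apply(m, 2, stats::quantile, probs = probs,
                              names = FALSE))
  ci <- list(lambda = stats::quantile(draws$lambda, probs, names = FALSE),
             q = qmat(draws$q), tau = qmat(draws$tau),
             n_tau = qmat(draws$n_tau),
             level = level, B = B, B_used = B - dropped)
  colnames(ci$q) <- colnames(ci$tau) <- colnames(ci$n_tau) <-
    base::c("lower", "upper")
  fit$ci <- ci
  fit$summary <- base_summary
  fit
}
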