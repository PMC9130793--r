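# Conceptual model of food-driven metabolic plasticity coupled to growth.
#
# RMR moves linearly toward an upper clamp at HIGH food and a lower clamp at
# LOW food (optionally after a lag), giving a piecewise-linear trajectory
# that is evaluated analytically. Growth is linear in time conditional on
# (food level, RMR): dM/dt = c(F) + d(F) * RMR(t), so mass is piecewise
# quadratic and is also integrated exactly.

#' Food schedule for a feeding-manipulation experiment
#'
#' @param start_days numeric vector of segment start days, strictly
#'   increasing, first element 0.
#' @param food_levels character vector, one of `"HIGH"`/`"LOW"` per segment.
#' @param total_days experiment horizon in days, greater than the last start.
#' @return An object of class `food_schedule`.
#' @examples
#' # five weeks high food then five weeks low food
#' food_schedule(c(0, 35), c("HIGH", "LOW"), 70)
#' @export
food_schedule <- function(start_days, food_levels, total_days) {
  food_levels <- toupper(as.character(food_levels))
  if (length(start_days) != length(food_levels))
    stop("start_days and food_levels must have the same length")
  if (start_days[1] != 0) stop("first segment must start at day 0")
  if (any(diff(start_days) <= 0)) stop("start_days must be strictly increasing")
  if (!all(food_levels %in% c("HIGH", "LOW")))
    stop("food_levels must be 'HIGH' or 'LOW'")
  if (total_days <= start_days[length(start_days)])
    stop("total_days must exceed the last segment start")
  structure(list(start_days = as.numeric(start_days),
                 food_levels = food_levels,
                 total_days = as.numeric(total_days)),
            class = "food_schedule")
}

#' Food level in force at given times
#'
#' @param schedule a [food_schedule()].
#' @param t numeric vector of days.
#' @return Character vector of `"HIGH"`/`"LOW"`.
#' @export
food_level_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "food_schedule"))
  idx <- findInterval(t, schedule$start_days, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  schedule$food_levels[idx]
}

#' Plasticity parameters: rates, clamps and lags
#'
#' @param rate_up weekly RMR increase at HIGH food (mg O2 g^-1 h^-1 wk^-1,
#'   non-negative).
#' @param rate_down weekly RMR decrease at LOW food, stored as a magnitude
#'   (non-negative).
#' @param rmr_min,rmr_max lower/upper clamps on RMR.
#' @param lag_up_days,lag_down_days delay after a switch before the RMR trend
#'   changes (days, default 0; RMR holds its value during the lag).
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(rate_up = 0.0038, rate_down = 0.008,
                              rmr_min = 0.05, rmr_max = 0.5,
                              lag_up_days = 0, lag_down_days = 0) {
  if (rate_up < 0 || rate_down < 0) stop("rates must be >= 0")
  if (rmr_min >= rmr_max) stop("rmr_min must be < rmr_max")
  if (lag_up_days < 0 || lag_down_days < 0) stop("lags must be >= 0")
  structure(list(rate_up = rate_up, rate_down = rate_down,
                 rmr_min = rmr_min, rmr_max = rmr_max,
                 lag_up_days = lag_up_days, lag_down_days = lag_down_days),
            class = "plasticity_params")
}

#' Growth parameters: linear growth conditional on food level and RMR
#'
#' Formalizes "growth is linear for a given combination of food supply and
#' metabolic rate" as \eqn{dM/dt = c(F) + d(F)\,RMR}. The context-dependence
#' hypothesis (high RMR helps at high food, hurts at low food) corresponds to
#' `d_high > 0 > d_low`; set `context_dependent = TRUE` to enforce those
#' signs. The default leaves the signs free, because empirically the
#' compensatory-growth pattern corresponds to `d_high < 0`.
#'
#' @param c_high,c_low intercepts, g per day.
#' @param d_high,d_low RMR coefficients, g per day per unit RMR
#'   (mg O2 g^-1 h^-1).
#' @param context_dependent logical; if `TRUE`, require `d_high > 0` and
#'   `d_low < 0`.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(c_high, d_high, c_low, d_low,
                          context_dependent = FALSE) {
  if (context_dependent && !(d_high > 0 && d_low < 0))
    stop("context dependence requires d_high > 0 and d_low < 0")
  structure(list(c = c(HIGH = c_high, LOW = c_low),
                 d = c(HIGH = d_high, LOW = d_low),
                 context_dependent = context_dependent),
            class = "growth_params")
}

# Piecewise-linear knot representation of the RMR trajectory:
# data.frame(t, v) with rmr linear between consecutive knots.
.rmr_knots <- function(params, schedule, rmr0) {
  t <- 0
  v <- rmr0
  kt <- 0
  kv <- rmr0
  starts <- schedule$start_days
  ends <- c(starts[-1], schedule$total_days)
  for (i in seq_along(starts)) {
    level <- schedule$food_levels[i]
    lag <- if (level == "HIGH") params$lag_up_days else params$lag_down_days
    slope <- if (level == "HIGH") params$rate_up / 7 else -params$rate_down / 7
    clamp <- if (level == "HIGH") params$rmr_max else params$rmr_min
    seg_end <- ends[i]
    t_eff <- min(starts[i] + lag, seg_end)
    if (t_eff > t) { # hold during lag
      kt <- c(kt, t_eff); kv <- c(kv, v)
      t <- t_eff
    }
    if (slope != 0 && v != clamp) {
      t_cross <- t + (clamp - v) / slope
      if (t_cross <= seg_end) {
        kt <- c(kt, t_cross); kv <- c(kv, clamp)
        v <- clamp
        t <- t_cross
        if (seg_end > t) {
          kt <- c(kt, seg_end); kv <- c(kv, v)
          t <- seg_end
        }
      } else {
        v <- v + slope * (seg_end - t)
        kt <- c(kt, seg_end); kv <- c(kv, v)
        t <- seg_end
      }
    } else if (seg_end > t) { # zero rate or already at the clamp: hold
      kt <- c(kt, seg_end); kv <- c(kv, v)
      t <- seg_end
    }
  }
  keep <- !duplicated(kt)
  data.frame(t = kt[keep], v = kv[keep])
}

#' Simulate the RMR trajectory under a food schedule
#'
#' Evaluates the rate-limited, clamped (optionally lagged) RMR trajectory
#' analytically: within each schedule segment, after the applicable lag, RMR
#' changes at `+rate_up/7` or `-rate_down/7` per day until it reaches the
#' relevant clamp. The trajectory is exactly piecewise linear, so grid values
#' are interpolated from the analytic knots with no integration error.
#'
#' @param params a [plasticity_params()].
#' @param schedule a [food_schedule()].
#' @param rmr0 initial RMR (mg O2 g^-1 h^-1), within the clamps.
#' @param dt_days grid spacing in days (default 1). Ignored when
#'   `times` is supplied.
#' @param times optional explicit day grid.
#' @return An object of class `rmr_trajectory`: list with `time_days`, `rmr`,
#'   the analytic `knots`, `schedule` and `params`.
#' @export
simulate_rmr <- function(params, schedule, rmr0, dt_days = 1, times = NULL) {
  stopifnot(inherits(params, "plasticity_params"),
            inherits(schedule, "food_schedule"))
  if (rmr0 < params$rmr_min || rmr0 > params$rmr_max)
    stop("rmr0 outside [rmr_min, rmr_max]")
  if (is.null(times)) {
    if (dt_days <= 0) stop("dt_days must be positive")
    times <- seq(0, schedule$total_days, by = dt_days)
    if (times[length(times)] < schedule$total_days)
      times <- c(times, schedule$total_days)
  }
  if (any(times < 0 | times > schedule$total_days))
    stop("times outside [0, total_days]")
  knots <- .rmr_knots(params, schedule, rmr0)
  rmr <- stats::approx(knots$t, knots$v, xout = times, rule = 2)$y
  structure(list(time_days = times, rmr = rmr, knots = knots,
                 schedule = schedule, params = params),
            class = "rmr_trajectory")
}

#' @export
print.rmr_trajectory <- function(x, ...) {
  cat("RMR trajectory over", x$schedule$total_days, "days:",
      sprintf("start %.4f, end %.4f mg O2/g/h\n",
              x$rmr[1], x$rmr[length(x$rmr)]))
  invisible(x)
}

#' @export
plot.rmr_trajectory <- function(x, ...) {
  graphics::plot(x$time_days, x$rmr, type = "l",
                 xlab = "day", ylab = "RMR (mg O2/g/h)", ...)
  graphics::abline(v = x$schedule$start_days[-1], lty = 3)
  invisible(x)
}

#' Simulate the mass trajectory implied by an RMR trajectory
#'
#' Integrates \eqn{dM/dt = c(F(t)) + d(F(t))\,RMR(t)} exactly: RMR is linear
#' between knots and (c, d) are constant within a schedule segment, so each
#' interval contributes a linear plus quadratic term, evaluated by the
#' trapezoid rule on the union of RMR knots, schedule boundaries and grid
#' times (exact for a linear integrand). Mass is floored at 0.
#'
#' @param growth a [growth_params()].
#' @param rmr_traj an [simulate_rmr()] result.
#' @param m0 initial mass, grams (> 0).
#' @return An object of class `mass_trajectory`: list with `time_days`,
#'   `mass`, `rmr`, the schedule and parameters.
#' @export
simulate_mass <- function(growth, rmr_traj, m0) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(rmr_traj, "rmr_trajectory"))
  if (m0 <= 0) stop("m0 must be positive")
  schedule <- rmr_traj$schedule
  grid <- rmr_traj$time_days
  tt <- sort(unique(c(rmr_traj$knots$t, schedule$start_days,
                      schedule$total_days, grid)))
  vv <- stats::approx(rmr_traj$knots$t, rmr_traj$knots$v, xout = tt,
                      rule = 2)$y
  # food level on each interval (t_i, t_{i+1}): take its midpoint
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  lev <- food_level_at(schedule, mid)
  dt <- diff(tt)
  vbar <- (vv[-1] + vv[-length(vv)]) / 2
  dM <- unname(growth$c[lev] + growth$d[lev] * vbar) * dt
  M <- m0 + c(0, cumsum(dM))
  M <- pmax(M, 0)
  mass <- M[match(grid, tt)]
  structure(list(time_days = grid, mass = mass,
                 rmr = stats::approx(rmr_traj$knots$t, rmr_traj$knots$v,
                                     xout = grid, rule = 2)$y,
                 schedule = schedule, growth = growth),
            class = "mass_trajectory")
}

#' @export
print.mass_trajectory <- function(x, ...) {
  cat("Mass trajectory over", x$schedule$total_days, "days:",
      sprintf("start %.1f g, end %.1f g\n", x$mass[1],
              x$mass[length(x$mass)]))
  invisible(x)
}

#' @export
plot.mass_trajectory <- function(x, ...) {
  graphics::plot(x$time_days, x$mass, type = "l",
                 xlab = "day", ylab = "mass (g)", ...)
  graphics::abline(v = x$schedule$start_days[-1], lty = 3)
  invisible(x)
}

#' Conceptual predictions: rapid vs slow plasticity under crossed schedules
#'
#' Generates the four scenario trajectories (fast/slow plasticity crossed
#' with high-to-low and low-to-high food schedules, switch at mid-horizon)
#' that illustrate how the rate of metabolic plasticity shapes growth. Both
#' organisms start at the midpoint RMR `(rmr_min + rmr_max)/2`.
#'
#' @param fast,slow [plasticity_params()] for the rapid and slow phenotype;
#'   the fast rates must exceed the slow rates.
#' @param growth a [growth_params()].
#' @param horizon_days experiment length; food switches at `horizon_days/2`.
#' @param m0 start mass in grams (default 100).
#' @param dt_days evaluation grid spacing (default 0.5).
#' @return An object of class `conceptual_prediction`: a named list of four
#'   scenarios (`fast_HL`, `fast_LH`, `slow_HL`, `slow_LH`), each holding an
#'   `rmr_trajectory` and a `mass_trajectory`.
#' @export
predict_conceptual_figure <- function(fast, slow, growth, horizon_days,
                                      m0 = 100, dt_days = 0.5) {
  stopifnot(inherits(fast, "plasticity_params"),
            inherits(slow, "plasticity_params"),
            inherits(growth, "growth_params"))
  if (!(fast$rate_up > slow$rate_up && fast$rate_down > slow$rate_down))
    stop("fast plasticity rates must exceed slow rates")
  mid_fast <- (fast$rmr_min + fast$rmr_max) / 2
  mid_slow <- (slow$rmr_min + slow$rmr_max) / 2
  half <- horizon_days / 2
  hl <- food_schedule(c(0, half), c("HIGH", "LOW"), horizon_days)
  lh <- food_schedule(c(0, half), c("LOW", "HIGH"), horizon_days)
  scen <- function(p, sched, r0) {
    r <- simulate_rmr(p, sched, r0, dt_days = dt_days)
    list(rmr = r, mass = simulate_mass(growth, r, m0))
  }
  structure(list(fast_HL = scen(fast, hl, mid_fast),
                 fast_LH = scen(fast, lh, mid_fast),
                 slow_HL = scen(slow, hl, mid_slow),
                 slow_LH = scen(slow, lh, mid_slow)),
            class = "conceptual_prediction")
}

#' @export
plot.conceptual_prediction <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- x$fast_HL$rmr
  ylim <- range(sapply(x, function(s) range(s$rmr$rmr)))
  graphics::plot(r$time_days, r$rmr, type = "l", ylim = ylim,
                 xlab = "day", ylab = "RMR (mg O2/g/h)")
  graphics::lines(x$fast_LH$rmr$time_days, x$fast_LH$rmr$rmr)
  graphics::lines(x$slow_HL$rmr$time_days, x$slow_HL$rmr$rmr, lty = 2)
  graphics::lines(x$slow_LH$rmr$time_days, x$slow_LH$rmr$rmr, lty = 2)
  ylim <- range(sapply(x, function(s) range(s$mass$mass)))
  m <- x$fast_HL$mass
  graphics::plot(m$time_days, m$mass, type = "l", ylim = ylim,
                 xlab = "day", ylab = "mass (g)")
  graphics::lines(x$fast_LH$mass$time_days, x$fast_LH$mass$mass)
  graphics::lines(x$slow_HL$mass$time_days, x$slow_HL$mass$mass, lty = 2)
  graphics::lines(x$slow_LH$mass$time_days, x$slow_LH$mass$mass, lty = 2)
  invisible(x)
}
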