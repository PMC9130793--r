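# Rate-limited, clamped RMR plasticity and coupled linear growth.

test_that("simulate_rmr evaluates the clamped piecewise-linear model exactly", {
  low35 <- food_schedule(0, "LOW", 35)

  # zero rates: constant trajectory
  p0 <- plasticity_params(rate_up = 0, rate_down = 0)
  tr <- simulate_rmr(p0, low35, rmr0 = 0.25)
  expect_true(all(tr$rmr == 0.25))

  # five weeks of decline at the fitted low-food rate from the pooled
  # baseline reproduces the switch-time group mean
  p <- plasticity_params(rate_down = 0.008)
  tr <- simulate_rmr(p, low35, rmr0 = 0.211, times = c(0, 35))
  expect_equal(tr$rmr[2], 0.211 - 5 * 0.008, tolerance = 1e-12)

  # clamp crossing at gap/rate: (0.211 - 0.19) / (0.008/7) = 18.375 d
  pc <- plasticity_params(rate_down = 0.008, rmr_min = 0.19, rmr_max = 0.5)
  t_cross <- (0.211 - 0.19) / (0.008 / 7)
  expect_equal(t_cross, 18.375)
  trc <- simulate_rmr(pc, low35, rmr0 = 0.211,
                      times = c(0, 10, t_cross, 20, 35))
  expect_equal(trc$rmr[3], 0.19, tolerance = 1e-12)
  expect_equal(trc$rmr[4:5], c(0.19, 0.19))
  # dense brute-force stepping agrees everywhere
  orc <- step_oracle(pc, low35, growth_params(0, 0, 0, 0), 0.211, 100,
                     dt = 5e-4)
  sim <- simulate_rmr(pc, low35, rmr0 = 0.211, times = orc$time_days)
  expect_lt(max(abs(sim$rmr - orc$rmr)), 1e-5)

  expect_error(simulate_rmr(pc, low35, rmr0 = 0.1), "outside")
})

test_that("lags hold the RMR constant before the trend sets in", {
  sched <- food_schedule(c(0, 35), c("LOW", "HIGH"), 70)
  p <- plasticity_params(rate_up = 0.007, rate_down = 0.008,
                         lag_up_days = 7, lag_down_days = 3)
  tr <- simulate_rmr(p, sched, rmr0 = 0.25,
                     times = c(0, 3, 10, 35, 42, 49))
  expect_equal(tr$rmr[2], 0.25)                             # in down-lag
  expect_equal(tr$rmr[3], 0.25 - 7 * 0.008 / 7)             # 7 d past lag
  r35 <- 0.25 - (35 - 3) * 0.008 / 7
  expect_equal(tr$rmr[4], r35, tolerance = 1e-12)
  expect_equal(tr$rmr[5], r35)                              # in up-lag
  expect_equal(tr$rmr[6], r35 + 7 * 0.007 / 7, tolerance = 1e-12)
})

test_that("simulate_mass integrates c(F) + d(F) RMR exactly", {
  sched <- food_schedule(c(0, 35), c("HIGH", "LOW"), 70)
  p <- plasticity_params(rate_up = 0.0038, rate_down = 0.008)
  tr <- simulate_rmr(p, sched, rmr0 = 0.21, dt_days = 1)

  # zero dynamics: constant mass
  m0 <- simulate_mass(growth_params(0, 0, 0, 0), tr, 100)
  expect_true(all(m0$mass == 100))

  # constant RMR and d = 0: mass rises exactly 1 g/day
  tr_const <- simulate_rmr(plasticity_params(0, 0), sched, 0.21, dt_days = 1)
  m1 <- simulate_mass(growth_params(1, 0, 1, 0), tr_const, 100)
  expect_equal(m1$mass, 100 + tr_const$time_days, tolerance = 1e-12)

  # quadratic segments match a dense trapezoid-stepping oracle
  g <- growth_params(2.3, -5, 0.35, -3)
  m2 <- simulate_mass(g, tr, 109)
  orc <- step_oracle(p, sched, g, 0.21, 109, dt = 0.001)
  at <- match(tr$time_days, round(orc$time_days, 6))
  expect_lt(max(abs(m2$mass - orc$mass[at])), 1e-4)
})

test_that("conceptual predictions obey symmetry and degenerate limits", {
  # mirrored world: rate_up = rate_down, symmetric clamps, growth dynamics
  # mirrored about the midpoint RMR -> HL mass is the mirror image of LH
  p_fast <- plasticity_params(rate_up = 0.02, rate_down = 0.02,
                              rmr_min = 0.1, rmr_max = 0.3)
  p_slow <- plasticity_params(rate_up = 0.004, rate_down = 0.004,
                              rmr_min = 0.1, rmr_max = 0.3)
  mid <- 0.2
  d_h <- 5
  c_h <- 1
  g_mirror <- growth_params(c_h, d_h, -c_h - 2 * d_h * mid, d_h)
  pred <- predict_conceptual_figure(p_fast, p_slow, g_mirror,
                                    horizon_days = 70, m0 = 100)
  for (who in c("fast", "slow")) {
    hl <- pred[[paste0(who, "_HL")]]$mass$mass
    lh <- pred[[paste0(who, "_LH")]]$mass$mass
    expect_equal(hl - 100, -(lh - 100), tolerance = 1e-10)
  }

  # zero-rate organism never leaves the midpoint; its growth is piecewise
  # linear with exactly one slope per food level
  p_zero <- plasticity_params(rate_up = 0, rate_down = 0,
                              rmr_min = 0.1, rmr_max = 0.3)
  g_cd <- growth_params(1, 5, -0.2, -4, context_dependent = TRUE)
  pred2 <- predict_conceptual_figure(p_fast, p_zero, g_cd,
                                     horizon_days = 70, m0 = 100)
  expect_true(all(pred2$slow_HL$rmr$rmr == mid))
  mass <- pred2$slow_HL$mass
  half <- which(mass$time_days <= 35)
  d1 <- diff(mass$mass[half]) / diff(mass$time_days[half])
  expect_lt(diff(range(d1)), 1e-10)

  # fast organism reaches the clamp before the switch; with d_high > 0 it
  # gains more mass pre-switch than the slow one
  pred3 <- predict_conceptual_figure(p_fast, p_slow, g_cd,
                                     horizon_days = 70, m0 = 100)
  at35 <- function(s) s$mass$mass[s$mass$time_days == 35]
  expect_equal(max(pred3$fast_HL$rmr$rmr), 0.3)
  expect_lt(max(pred3$slow_HL$rmr$rmr), 0.3)
  expect_gt(at35(pred3$fast_HL), at35(pred3$slow_HL))

  expect_error(predict_conceptual_figure(p_slow, p_fast, g_cd, 70),
               "exceed")
})

test_that("clamping, mismatch duration and curvature invariants hold", {
  set.seed(4)
  for (i in 1:25) {
    rmin <- runif(1, 0.05, 0.15)
    rmax <- rmin + runif(1, 0.05, 0.3)
    p <- plasticity_params(rate_up = runif(1, 0, 0.05),
                           rate_down = runif(1, 0, 0.05),
                           rmr_min = rmin, rmr_max = rmax)
    n_seg <- sample(1:4, 1)
    starts <- c(0, sort(sample(1:69, n_seg - 1)))
    sched <- food_schedule(starts,
                           sample(c("HIGH", "LOW"), n_seg, replace = TRUE),
                           70)
    tr <- simulate_rmr(p, sched, runif(1, rmin, rmax), dt_days = 0.25)
    expect_true(all(tr$rmr >= rmin - 1e-12 & tr$rmr <= rmax + 1e-12))
  }

  # mismatch duration: time from switch to clamp equals gap/rate exactly
  sched <- food_schedule(c(0, 35), c("HIGH", "LOW"), 200)
  p <- plasticity_params(rate_up = 0.01, rate_down = 0.02,
                         rmr_min = 0.1, rmr_max = 0.26)
  tr <- simulate_rmr(p, sched, 0.2, dt_days = 1)
  r35 <- 0.2 + 35 * 0.01 / 7
  t_pred <- 35 + (r35 - 0.1) / (0.02 / 7)
  k <- tr$knots
  expect_equal(k$t[k$v == 0.1][1], t_pred, tolerance = 1e-10)

  # monotone-in-rate: at LOW food with d_low < 0, faster downregulation
  # never yields less final mass
  g <- growth_params(1, 5, -0.2, -4, context_dependent = TRUE)
  low <- food_schedule(0, "LOW", 70)
  finals <- vapply(seq(0.002, 0.03, by = 0.004), function(rd) {
    pp <- plasticity_params(rate_up = 0, rate_down = rd,
                            rmr_min = 0.1, rmr_max = 0.3)
    tr <- simulate_rmr(pp, low, 0.25, dt_days = 1)
    tail(simulate_mass(g, tr, 100)$mass, 1)
  }, 0)
  expect_true(all(diff(finals) >= -1e-10))

  # curvature diagnostic: second differences of mass vanish exactly where
  # RMR is constant and are nonzero while RMR is changing (d != 0)
  pc <- plasticity_params(rate_up = 0, rate_down = 0.02,
                          rmr_min = 0.15, rmr_max = 0.3)
  tr <- simulate_rmr(pc, low, 0.25, dt_days = 1)   # clamps at t = 35
  m <- simulate_mass(g, tr, 100)
  d2 <- diff(m$mass, differences = 2)
  # the point at t = 35 spans the kink itself, so it belongs to "moving"
  moving <- tr$time_days[2:(length(tr$time_days) - 1)] <= 35
  expect_true(all(abs(d2[moving]) > 1e-10))
  expect_true(all(abs(d2[!moving]) < 1e-10))
})
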