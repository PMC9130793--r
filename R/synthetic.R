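# Seeded generator of synthetic crossover feeding experiments.
#
# Emulates a 16-fish high/low food crossover: two groups (HL: high food then
# low; LH: low then high), weekly RMR + mass measurements, prey-fish feeding
# events, individual variation in baseline RMR, measurement noise and rare
# additive outliers. True trajectories come from the plasticity/growth
# simulator, so the generating process matches what the analysis assumes.

#' Configuration of a synthetic crossover feeding experiment
#'
#' Defaults describe a 16-fish experiment: 7 fish switched high-to-low (HL)
#' and 9 low-to-high (LH), 11 weekly measurement events with the food switch
#' after five weeks, start masses ~109 +/- 20 g (66-141 g), prey masses
#' ~6.7 +/- 3.3 g (1.6-21.6 g), baseline RMR ~0.211 mg O2 g^-1 h^-1 with
#' between-fish sd 0.04 and measurement sd 0.015, weekly plasticity rates
#' +0.0038 (high food) and -0.008 (low food), and outliers injected at ~1.7 %
#' of measurements. Growth parameters are calibrated so high-food gain is
#' roughly +1 % body mass per day, low-food loss is slow, and the LH group
#' out-grows the HL group at high food (compensatory growth: `d_high < 0`).
#'
#' @param n_hl,n_lh fish per group.
#' @param weeks_per_phase weeks before the food switch (each phase).
#' @param n_measurement_events weekly measurement events (day 0 onward).
#' @param start_mass_mean_g,start_mass_sd_g,start_mass_range truncated-Normal
#'   start-mass distribution (g).
#' @param prey_mass_mean_g,prey_mass_sd_g,prey_mass_range truncated-Normal
#'   prey-mass distribution (g).
#' @param feeds_per_week named vector: prey fish offered per week at each
#'   food level.
#' @param rmr0_mean,rmr0_between_individual_sd baseline RMR distribution
#'   (truncated at mean +/- 2.5 sd).
#' @param rmr_measurement_sd sd of Gaussian RMR measurement noise.
#' @param mass_measurement_cv coefficient of variation of multiplicative
#'   wet-weighing error (default 0.005, i.e. ~0.5 g on a 110 g fish:
#'   scale resolution plus surface water and gut-content variation).
#' @param rate_up,rate_down weekly plasticity rates (magnitudes).
#' @param rmr_min,rmr_max RMR clamps (wide defaults: non-binding at the
#'   default rates over five weeks).
#' @param growth a [growth_params()] object.
#' @param outlier_probability,outlier_magnitude_sd per-measurement outlier
#'   probability and sd of the additive shock.
#' @param day_jitter_days measurement days are jittered by a uniform integer
#'   in `[-day_jitter_days, day_jitter_days]` (day-0 event kept at 0).
#' @param consumed_probability probability an offered prey fish is eaten.
#' @param week6_underfeeding if `TRUE`, high-food fish are fed only three
#'   times in the first week after the switch (a recorded husbandry slip).
#' @param seed default seed used by [generate_experiment()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_hl = 7, n_lh = 9,
                              weeks_per_phase = 5,
                              n_measurement_events = 11,
                              start_mass_mean_g = 109, start_mass_sd_g = 20,
                              start_mass_range = c(66, 141),
                              prey_mass_mean_g = 6.7, prey_mass_sd_g = 3.3,
                              prey_mass_range = c(1.6, 21.6),
                              feeds_per_week = c(HIGH = 4, LOW = 1),
                              rmr0_mean = 0.211,
                              rmr0_between_individual_sd = 0.04,
                              rmr_measurement_sd = 0.015,
                              mass_measurement_cv = 0.005,
                              rate_up = 0.0038, rate_down = 0.008,
                              rmr_min = 0.05, rmr_max = 0.5,
                              growth = growth_params(2.3, -5.0, 0.35, -3.0),
                              outlier_probability = 0.017,
                              outlier_magnitude_sd = 0.08,
                              day_jitter_days = 1,
                              consumed_probability = 0.96,
                              week6_underfeeding = FALSE,
                              seed = 1L) {
  stopifnot(n_hl > 0, n_lh > 0, weeks_per_phase > 0,
            n_measurement_events > 2,
            start_mass_sd_g >= 0, prey_mass_sd_g >= 0,
            rmr0_between_individual_sd >= 0, rmr_measurement_sd >= 0,
            mass_measurement_cv >= 0,
            outlier_probability >= 0, outlier_probability <= 1,
            consumed_probability >= 0, consumed_probability <= 1,
            day_jitter_days >= 0)
  if (start_mass_mean_g < start_mass_range[1] ||
      start_mass_mean_g > start_mass_range[2])
    stop("start_mass_range must contain start_mass_mean_g")
  if (prey_mass_mean_g < prey_mass_range[1] ||
      prey_mass_mean_g > prey_mass_range[2])
    stop("prey_mass_range must contain prey_mass_mean_g")
  stopifnot(inherits(growth, "growth_params"))
  structure(as.list(environment()), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Synthetic crossover experiment config:",
      x$n_hl, "HL +", x$n_lh, "LH fish,",
      x$n_measurement_events, "weekly events, switch after",
      x$weeks_per_phase, "weeks\n")
  cat(sprintf("  rates +%.4f / -%.4f per wk, baseline %.3f (sd %.3f), noise sd %.3f\n",
              x$rate_up, x$rate_down, x$rmr0_mean,
              x$rmr0_between_individual_sd, x$rmr_measurement_sd))
  invisible(x)
}

#' Truncated-Normal sampler
#'
#' Inverse-CDF sampler for Normal(mean, sd) truncated to `[lower, upper]`.
#'
#' @param n sample size.
#' @param mean,sd Normal parameters.
#' @param lower,upper truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= upper) stop("impossible truncation bounds")
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("impossible truncation bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) stop("impossible truncation bounds")
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Food schedule of one treatment group
#'
#' @param config an [experiment_config()].
#' @param group `"HL"` (high food first) or `"LH"`.
#' @return A [food_schedule()] spanning the whole measurement period.
#' @export
schedule_for_group <- function(config, group) {
  switch_day <- config$weeks_per_phase * 7
  total_days <- (config$n_measurement_events - 1) * 7
  levels <- if (group == "HL") c("HIGH", "LOW") else c("LOW", "HIGH")
  food_schedule(c(0, switch_day), levels, total_days)
}

#' Plasticity parameters implied by a config
#'
#' @param config an [experiment_config()].
#' @return A [plasticity_params()] with zero lags.
#' @export
plasticity_from_config <- function(config) {
  plasticity_params(rate_up = config$rate_up, rate_down = config$rate_down,
                    rmr_min = config$rmr_min, rmr_max = config$rmr_max)
}

#' Generate a complete synthetic crossover experiment
#'
#' Deterministic given the seed. Per fish: a baseline RMR drawn from a
#' truncated Normal, a true RMR trajectory from [simulate_rmr()], a mass
#' trajectory from [simulate_mass()], weekly measurement days jittered by up
#' to `day_jitter_days`, observed RMR = true + Gaussian noise with rare
#' additive outlier shocks (flagged in the output), and weekly feeding events
#' with truncated-Normal prey masses and Bernoulli consumption.
#'
#' @param config an [experiment_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `experiment_dataset`: list of data frames
#'   `individuals` (fish_id, group, start_mass_g, true_rmr0), `measurements`
#'   (fish_id, group, event_index, day, days_in_phase, food_level, rmr_true,
#'   rmr_observed, mass_g, is_injected_outlier) and `feedings` (fish_id,
#'   group, week, day, food_level, prey_mass_g, consumed), plus the `config`.
#' @export
generate_experiment <- function(config = experiment_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  .with_seed(seed, {
    n <- config$n_hl + config$n_lh
    fish_id <- sprintf("F%02d", seq_len(n))
    group <- c(rep("HL", config$n_hl), rep("LH", config$n_lh))
    start_mass <- rtruncnorm(n, config$start_mass_mean_g,
                             config$start_mass_sd_g,
                             config$start_mass_range[1],
                             config$start_mass_range[2])
    r_sd <- config$rmr0_between_individual_sd
    rmr0 <- rtruncnorm(n, config$rmr0_mean, r_sd,
                       max(config$rmr_min, config$rmr0_mean - 2.5 * r_sd),
                       min(config$rmr_max, config$rmr0_mean + 2.5 * r_sd))
    individuals <- data.frame(fish_id = fish_id, group = group,
                              start_mass_g = start_mass, true_rmr0 = rmr0,
                              rate_up = config$rate_up,
                              rate_down = config$rate_down)
    params <- plasticity_from_config(config)
    switch_day <- config$weeks_per_phase * 7
    total_days <- (config$n_measurement_events - 1) * 7
    n_ev <- config$n_measurement_events
    nominal <- 7 * (seq_len(n_ev) - 1)

    meas <- vector("list", n)
    feeds <- vector("list", n)
    n_weeks <- n_ev - 1
    for (i in seq_len(n)) {
      sched <- schedule_for_group(config, group[i])
      j <- config$day_jitter_days
      jit <- if (j > 0) sample(seq(-j, j), n_ev - 1, replace = TRUE)
             else integer(n_ev - 1)
      days <- nominal + c(0, jit)
      days <- pmin(pmax(days, 0), total_days)
      traj <- simulate_rmr(params, sched, rmr0[i], times = days)
      mass <- simulate_mass(config$growth, traj, start_mass[i])
      phase <- ifelse(days <= switch_day, 1L, 2L)
      lev <- ifelse(phase == 1L, sched$food_levels[1], sched$food_levels[2])
      rmr_obs <- traj$rmr +
        stats::rnorm(n_ev, 0, config$rmr_measurement_sd)
      mass_obs <- mass$mass *
        exp(stats::rnorm(n_ev, 0, config$mass_measurement_cv))
      is_out <- stats::runif(n_ev) < config$outlier_probability
      rmr_obs[is_out] <- rmr_obs[is_out] +
        stats::rnorm(sum(is_out), 0, config$outlier_magnitude_sd)
      meas[[i]] <- data.frame(
        fish_id = fish_id[i], group = group[i],
        event_index = seq_len(n_ev) - 1L, day = days,
        days_in_phase = ifelse(phase == 1L, days, days - switch_day),
        food_level = lev, rmr_true = traj$rmr, rmr_observed = rmr_obs,
        mass_true_g = mass$mass, mass_g = mass_obs,
        is_injected_outlier = is_out)

      fw <- lapply(seq_len(n_weeks), function(w) {
        week_level <- if (w <= config$weeks_per_phase)
          sched$food_levels[1] else sched$food_levels[2]
        nf <- unname(config$feeds_per_week[week_level])
        if (config$week6_underfeeding && week_level == "HIGH" &&
            w == config$weeks_per_phase + 1)
          nf <- nf - 1L
        if (nf <= 0) return(NULL)
        data.frame(fish_id = fish_id[i], group = group[i], week = w,
                   day = 7 * (w - 1) + seq_len(nf),
                   food_level = week_level,
                   prey_mass_g = rtruncnorm(nf, config$prey_mass_mean_g,
                                            config$prey_mass_sd_g,
                                            config$prey_mass_range[1],
                                            config$prey_mass_range[2]),
                   consumed = stats::runif(nf) < config$consumed_probability)
      })
      feeds[[i]] <- do.call(rbind, fw)
    }
    measurements <- do.call(rbind, meas)
    feedings <- do.call(rbind, feeds)
    rownames(measurements) <- rownames(feedings) <- NULL
    structure(list(individuals = individuals, measurements = measurements,
                   feedings = feedings, config = config, seed = seed),
              class = "experiment_dataset")
  })
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat("Synthetic crossover experiment (seed", paste0(x$seed, "):"),
      nrow(x$individuals), "fish,",
      nrow(x$measurements), "measurements,",
      nrow(x$feedings), "feeding events\n")
  invisible(x)
}

#' @export
summary.experiment_dataset <- function(object, ...) {
  m <- object$measurements
  cat("Groups:", paste(names(table(object$individuals$group)),
                       table(object$individuals$group),
                       collapse = ", ", sep = " = "), "\n")
  cat(sprintf("Start mass: %.1f +/- %.1f g | baseline RMR: %.3f +/- %.3f\n",
              mean(object$individuals$start_mass_g),
              stats::sd(object$individuals$start_mass_g),
              mean(object$individuals$true_rmr0),
              stats::sd(object$individuals$true_rmr0)))
  cat(sprintf("Injected outliers: %d of %d measurements\n",
              sum(m$is_injected_outlier), nrow(m)))
  invisible(object)
}

#' Generate a synthetic closed-chamber oxygen trace
#'
#' Inverts the MO2 formula: a linear oxygen decline with volumetric slope
#' `target_mo2 * M_f / (V_r - V_f)` plus optional Gaussian noise. The
#' saturation concentration is set to the starting concentration, and the
#' default duration is short enough that the 80 % cutoff is not reached at
#' typical fish metabolic rates.
#'
#' @param target_mo2 mass-specific metabolic rate to encode (>= 0).
#' @param fish_mass_g,chamber_volume_l chamber geometry.
#' @param duration_s,interval_s trace length and sampling interval (s).
#' @param noise_sd sd of Gaussian concentration noise (mg/L).
#' @param o2_start starting (air-saturated) concentration, mg/L.
#' @param seed optional seed.
#' @param assay_id,fish_id identifiers.
#' @return An [oxygen_trace()].
#' @export
generate_o2_trace <- function(target_mo2, fish_mass_g = 109,
                              chamber_volume_l = 3.1,
                              duration_s = 600, interval_s = 10,
                              noise_sd = 0, o2_start = 9.0, seed = NULL,
                              assay_id = "synthetic", fish_id = "F00") {
  if (target_mo2 < 0) stop("target_mo2 must be >= 0")
  gen <- function() {
    v_f <- fish_mass_g / 1000
    slope <- target_mo2 * fish_mass_g / (chamber_volume_l - v_f)
    time_s <- seq(0, duration_s, by = interval_s)
    o2 <- o2_start - slope * time_s / 3600
    if (noise_sd > 0) o2 <- o2 + stats::rnorm(length(o2), 0, noise_sd)
    oxygen_trace(assay_id, fish_id, time_s, o2,
                 chamber_volume_l = chamber_volume_l,
                 fish_mass_g = fish_mass_g,
                 o2_saturation_mg_per_l = o2_start)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Write an experiment dataset to CSV files
#'
#' Writes `individuals.csv`, `measurements.csv` and `feedings.csv` into
#' `outdir` (created if needed).
#'
#' @param dataset an [generate_experiment()] result.
#' @param outdir output directory.
#' @return Invisibly, the paths written.
#' @export
write_experiment_csvs <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir,
                     c("individuals.csv", "measurements.csv", "feedings.csv"))
  utils::write.csv(dataset$individuals, paths[1], row.names = FALSE)
  utils::write.csv(dataset$measurements, paths[2], row.names = FALSE)
  utils::write.csv(dataset$feedings, paths[3], row.names = FALSE)
  invisible(paths)
}
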