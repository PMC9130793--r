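# Simulation-recovery harness: generate -> clean -> fit over replicates.

#' Parameter-recovery study for the weekly plasticity rates
#'
#' Generates `replicates` independent synthetic experiments, runs the
#' cleaning and slope-estimation pipeline on each, and collects the pooled
#' food-level-specific weekly slopes. Used to check that the pipeline
#' recovers the generating rates (`+rate_up` at high food, `-rate_down` at
#' low food) without systematic bias.
#'
#' @param config an [experiment_config()].
#' @param replicates number of synthetic experiments.
#' @param seed base seed; replicate `i` uses `seed + i - 1`.
#' @param estimator passed to [fit_rmr_slopes()] (default `"two_stage"`).
#' @return An object of class `recovery_study`: a data frame with columns
#'   `replicate`, `seed`, `slope_high`, `slope_low` (pooled over groups) and
#'   `slope_hl_high`, `slope_lh_low` (the first-phase group slopes: high food
#'   in the HL group, low food in the LH group), with the generating rates in
#'   attributes `true_high` / `true_low`.
#' @export
recover_rates <- function(config = experiment_config(), replicates = 200,
                          seed = 1, estimator = "two_stage") {
  stopifnot(replicates >= 1)
  rows <- lapply(seq_len(replicates), function(i) {
    ds <- generate_experiment(config, seed = seed + i - 1)
    cleaned <- clean_outliers(ds$measurements)
    fit <- fit_rmr_slopes(cleaned, response = "rmr", estimator = estimator)
    p <- fit$pooled
    bg <- fit$by_group
    data.frame(replicate = i, seed = seed + i - 1,
               slope_high = p$slope[p$food_level == "HIGH"],
               slope_low = p$slope[p$food_level == "LOW"],
               slope_hl_high = bg$slope[bg$group == "HL" &
                                          bg$food_level == "HIGH"],
               slope_lh_low = bg$slope[bg$group == "LH" &
                                         bg$food_level == "LOW"])
  })
  out <- do.call(rbind, rows)
  attr(out, "true_high") <- config$rate_up
  attr(out, "true_low") <- -config$rate_down
  class(out) <- c("recovery_study", "data.frame")
  out
}

#' @export
print.recovery_study <- function(x, ...) {
  mh <- mean(x$slope_high); ml <- mean(x$slope_low)
  seh <- stats::sd(x$slope_high) / sqrt(nrow(x))
  sel <- stats::sd(x$slope_low) / sqrt(nrow(x))
  cat(sprintf("Recovery over %d replicates:\n", nrow(x)))
  cat(sprintf("  high-food slope: %+.5f (MC se %.5f), truth %+.5f\n",
              mh, seh, attr(x, "true_high")))
  cat(sprintf("  low-food slope:  %+.5f (MC se %.5f), truth %+.5f\n",
              ml, sel, attr(x, "true_low")))
  invisible(x)
}
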