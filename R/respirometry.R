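# Closed-chamber respirometry: oxygen traces -> mass-specific metabolic rate.

#' Construct an oxygen trace from one closed-chamber assay
#'
#' Represents the oxygen concentration recorded in a sealed respirometer
#' chamber holding a single fish, from valve closure until the assay was
#' terminated. Concentrations must be sampled at a constant interval
#' (typically 10 or 30 s) on a strictly increasing clock.
#'
#' @param assay_id,fish_id identifiers (coerced to character).
#' @param time_s numeric vector, seconds since chamber closure; strictly
#'   increasing, constant sampling interval.
#' @param o2_mg_per_l oxygen concentrations (mg O2 per litre), all positive.
#' @param chamber_volume_l respirometer water volume V_r in litres.
#' @param fish_mass_g wet mass M_f in grams. Fish volume is taken as
#'   `fish_mass_g / 1000` litres (fish assumed neutrally buoyant, density of
#'   water), and must be smaller than the chamber volume.
#' @param temperature_c assay temperature, degrees C (metadata only; no
#'   temperature correction is applied).
#' @param o2_saturation_mg_per_l concentration at 100 % air saturation, used
#'   for the saturation cutoff in [trim_trace()].
#' @return An object of class `oxygen_trace`.
#' @seealso [trim_trace()], [estimate_uptake_rate()], [compute_mo2()],
#'   [estimate_mo2()]
#' @export
oxygen_trace <- function(assay_id, fish_id, time_s, o2_mg_per_l,
                         chamber_volume_l, fish_mass_g,
                         temperature_c = NA_real_,
                         o2_saturation_mg_per_l = NA_real_) {
  time_s <- as.numeric(time_s)
  o2_mg_per_l <- as.numeric(o2_mg_per_l)
  if (length(time_s) != length(o2_mg_per_l))
    stop("time_s and o2_mg_per_l must have the same length")
  if (length(time_s) < 2L) stop("a trace needs at least two samples")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    stop("sampling interval must be constant within a trace")
  if (any(o2_mg_per_l <= 0)) stop("all oxygen concentrations must be > 0")
  if (!is.finite(chamber_volume_l) || chamber_volume_l <= 0)
    stop("chamber_volume_l must be positive")
  if (!is.finite(fish_mass_g) || fish_mass_g <= 0)
    stop("fish_mass_g must be positive")
  if (fish_mass_g / 1000 >= chamber_volume_l)
    stop("fish larger than chamber: fish volume >= chamber volume")
  structure(
    list(assay_id = as.character(assay_id),
         fish_id = as.character(fish_id),
         time_s = time_s,
         o2_mg_per_l = o2_mg_per_l,
         chamber_volume_l = chamber_volume_l,
         fish_mass_g = fish_mass_g,
         temperature_c = temperature_c,
         o2_saturation_mg_per_l = o2_saturation_mg_per_l),
    class = "oxygen_trace")
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat("Oxygen trace", x$assay_id, "(fish", paste0(x$fish_id, "):"),
      length(x$time_s), "samples over",
      round(diff(range(x$time_s)) / 60, 1), "min\n")
  cat("  O2:", round(min(x$o2_mg_per_l), 3), "-",
      round(max(x$o2_mg_per_l), 3), "mg/L | chamber",
      x$chamber_volume_l, "L | fish", x$fish_mass_g, "g\n")
  invisible(x)
}

#' Respirometry processing protocol
#'
#' Bundles the trace-processing conventions: the initial settling period to
#' discard (handling stress after valve closure), the air-saturation fraction
#' at which assays are truncated, a chamber-level background respiration rate
#' to subtract, and the minimum number of retained samples for a valid fit.
#'
#' @param discard_initial_s seconds discarded after closure (default 120,
#'   i.e. the first 2 min).
#' @param saturation_cutoff_fraction samples with O2 below this fraction of
#'   air saturation are dropped (default 0.80). Set to 0 to disable.
#' @param background_rate_mg_per_h background (microbial) respiration in
#'   mg O2 per hour, subtracted from whole-chamber uptake. Default 0:
#'   measured blanks are typically negligible.
#' @param min_points minimum retained samples for a valid fit (default 5,
#'   must be at least 3).
#' @return An object of class `respirometry_protocol`.
#' @export
respirometry_protocol <- function(discard_initial_s = 120,
                                  saturation_cutoff_fraction = 0.80,
                                  background_rate_mg_per_h = 0,
                                  min_points = 5L) {
  if (discard_initial_s < 0) stop("discard_initial_s must be >= 0")
  if (saturation_cutoff_fraction < 0 || saturation_cutoff_fraction >= 1)
    stop("saturation_cutoff_fraction must be in [0, 1)")
  if (min_points < 3) stop("min_points must be >= 3")
  structure(
    list(discard_initial_s = discard_initial_s,
         saturation_cutoff_fraction = saturation_cutoff_fraction,
         background_rate_mg_per_h = background_rate_mg_per_h,
         min_points = as.integer(min_points)),
    class = "respirometry_protocol")
}

#' Trim an oxygen trace per protocol
#'
#' Drops samples from the initial settling period (`time_s <
#' discard_initial_s`) and samples below the saturation cutoff
#' (`o2 < saturation_cutoff_fraction * o2_saturation_mg_per_l`). Values are
#' never modified, only filtered; ordering is preserved. A cutoff fraction of
#' 0, or a missing saturation value, disables the saturation filter.
#'
#' @param trace an [oxygen_trace()].
#' @param protocol a [respirometry_protocol()].
#' @return The trimmed `oxygen_trace`.
#' @export
trim_trace <- function(trace, protocol = respirometry_protocol()) {
  stopifnot(inherits(trace, "oxygen_trace"),
            inherits(protocol, "respirometry_protocol"))
  keep <- trace$time_s >= protocol$discard_initial_s
  if (protocol$saturation_cutoff_fraction > 0 &&
      is.finite(trace$o2_saturation_mg_per_l)) {
    keep <- keep & (trace$o2_mg_per_l >=
      protocol$saturation_cutoff_fraction * trace$o2_saturation_mg_per_l)
  }
  n_kept <- sum(keep)
  if (n_kept < protocol$min_points) {
    cond <- simpleError(sprintf(
      "trace too short: %d samples retained (minimum %d)",
      n_kept, protocol$min_points))
    cond$retained <- n_kept
    class(cond) <- c("trace_too_short", class(cond))
    stop(cond)
  }
  out <- trace
  out$time_s <- trace$time_s[keep]
  out$o2_mg_per_l <- trace$o2_mg_per_l[keep]
  out
}

# closed-form OLS of y on x; avoids lm() overhead in tight loops
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("zero variance in predictor")
  sxy <- sum((x - mx) * (y - my))
  b <- sxy / sxx
  a <- my - b * mx
  res <- y - (a + b * x)
  rss <- sum(res^2)
  tss <- sum((y - my)^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(intercept = a, slope = b, se = se, r_squared = r2, n = n)
}

#' Estimate the oxygen uptake slope of a (trimmed) trace
#'
#' Ordinary least-squares fit of oxygen concentration against time in hours.
#' The returned slope is the negated regression slope, so that oxygen
#' consumption is positive. A rising oxygen trace (apparent oxygen
#' production) yields a negative slope with a warning, not an error.
#'
#' @param trace an [oxygen_trace()], usually the output of [trim_trace()].
#' @return A list with `uptake_slope_mg_per_l_per_h` (positive =
#'   consumption), `slope_se`, `r_squared`, `n_points` and the logical
#'   `negative_consumption` flag.
#' @export
estimate_uptake_rate <- function(trace) {
  stopifnot(inherits(trace, "oxygen_trace"))
  if (length(trace$time_s) < 3) stop("need at least 3 samples for the fit")
  fit <- .ols(trace$time_s / 3600, trace$o2_mg_per_l)
  slope <- -fit$slope
  neg <- is.finite(slope) && slope < 0
  if (neg)
    warning("oxygen concentration rising: negative consumption slope")
  list(uptake_slope_mg_per_l_per_h = slope,
       slope_se = fit$se,
       r_squared = fit$r_squared,
       n_points = fit$n,
       negative_consumption = neg)
}

#' Mass-specific metabolic rate from an uptake slope
#'
#' Applies the closed-respirometry formula
#' \deqn{MO_2 = \frac{(V_r - V_f)\,\Delta O_2}{M_f}}
#' where \eqn{V_r} is the chamber water volume (L), \eqn{V_f = M_f/1000} is
#' the fish volume (fish assumed to have the density of water), \eqn{\Delta
#' O_2} the volumetric uptake slope (mg O2 L\eqn{^{-1}} h\eqn{^{-1}}) and
#' \eqn{M_f} the fish mass (g). An optional chamber-level background rate
#' (mg O2 h\eqn{^{-1}}) is subtracted from whole-chamber uptake first.
#'
#' @param slope volumetric uptake slope, mg O2 per litre per hour
#'   (consumption positive).
#' @param trace the [oxygen_trace()] supplying geometry (V_r, M_f).
#' @param protocol a [respirometry_protocol()]; supplies the background rate.
#' @param slope_se,r_squared,n_points optional fit statistics carried through
#'   into the result.
#' @return An object of class `metabolic_rate_estimate`: a list with
#'   `assay_id`, `fish_id`, `uptake_slope_mg_per_l_per_h`, `slope_se`,
#'   `r_squared`, `n_points`, `fish_volume_l` and `mo2_mg_per_g_per_h`.
#' @export
compute_mo2 <- function(slope, trace, protocol = respirometry_protocol(),
                        slope_se = NA_real_, r_squared = NA_real_,
                        n_points = NA_integer_) {
  stopifnot(inherits(trace, "oxygen_trace"))
  if (!is.finite(slope)) stop("slope must be finite")
  v_f <- trace$fish_mass_g / 1000
  v_r <- trace$chamber_volume_l
  if (v_f >= v_r) stop("fish larger than chamber")
  uptake_mg_per_h <- (v_r - v_f) * slope - protocol$background_rate_mg_per_h
  structure(
    list(assay_id = trace$assay_id,
         fish_id = trace$fish_id,
         uptake_slope_mg_per_l_per_h = slope,
         slope_se = slope_se,
         r_squared = r_squared,
         n_points = n_points,
         fish_volume_l = v_f,
         mo2_mg_per_g_per_h = uptake_mg_per_h / trace$fish_mass_g),
    class = "metabolic_rate_estimate")
}

#' @export
print.metabolic_rate_estimate <- function(x, ...) {
  cat(sprintf("MO2 estimate [%s]: %.4f mg O2/g/h (slope %.3f mg/L/h, n = %s, r2 = %s)\n",
              x$assay_id, x$mo2_mg_per_g_per_h, x$uptake_slope_mg_per_l_per_h,
              x$n_points, format(round(x$r_squared, 4))))
  invisible(x)
}

#' Full per-assay pipeline: trim, fit, convert
#'
#' Convenience wrapper running [trim_trace()], [estimate_uptake_rate()] and
#' [compute_mo2()] on one trace.
#'
#' @inheritParams trim_trace
#' @return A `metabolic_rate_estimate` (see [compute_mo2()]).
#' @export
estimate_mo2 <- function(trace, protocol = respirometry_protocol()) {
  trimmed <- trim_trace(trace, protocol)
  fit <- estimate_uptake_rate(trimmed)
  compute_mo2(fit$uptake_slope_mg_per_l_per_h, trimmed, protocol,
              slope_se = fit$slope_se, r_squared = fit$r_squared,
              n_points = fit$n_points)
}

#' Process a table of oxygen traces into MO2 estimates
#'
#' @param traces data frame with columns `assay_id`, `fish_id`, `time_s`,
#'   `o2_mg_per_l` (one row per sample).
#' @param meta data frame with one row per assay: `assay_id`,
#'   `chamber_volume_l`, `fish_mass_g`, and optionally `temperature_c`,
#'   `o2_saturation_mg_per_l`.
#' @param protocol a [respirometry_protocol()].
#' @return A data frame of metabolic-rate estimates, one row per assay.
#' @export
process_respirometry <- function(traces, meta,
                                 protocol = respirometry_protocol()) {
  need_t <- c("assay_id", "fish_id", "time_s", "o2_mg_per_l")
  need_m <- c("assay_id", "chamber_volume_l", "fish_mass_g")
  miss <- setdiff(need_t, names(traces))
  if (length(miss)) stop("traces: missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_m, names(meta))
  if (length(miss)) stop("meta: missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(traces, traces$assay_id), function(d) {
    m <- meta[match(d$assay_id[1], meta$assay_id), ]
    if (is.na(m$assay_id)) stop("no metadata for assay ", d$assay_id[1])
    tr <- oxygen_trace(
      assay_id = d$assay_id[1], fish_id = d$fish_id[1],
      time_s = d$time_s, o2_mg_per_l = d$o2_mg_per_l,
      chamber_volume_l = m$chamber_volume_l, fish_mass_g = m$fish_mass_g,
      temperature_c = if ("temperature_c" %in% names(m)) m$temperature_c else NA_real_,
      o2_saturation_mg_per_l = if ("o2_saturation_mg_per_l" %in% names(m))
        m$o2_saturation_mg_per_l else NA_real_)
    est <- estimate_mo2(tr, protocol)
    data.frame(assay_id = est$assay_id, fish_id = est$fish_id,
               uptake_slope_mg_per_l_per_h = est$uptake_slope_mg_per_l_per_h,
               slope_se = est$slope_se, r_squared = est$r_squared,
               n_points = est$n_points, fish_volume_l = est$fish_volume_l,
               mo2_mg_per_g_per_h = est$mo2_mg_per_g_per_h)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
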