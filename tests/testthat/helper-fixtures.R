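# Programmatic fixtures (no data files).

# linear oxygen trace: o2(t) = o2_start - slope_per_h * t_hours (+ noise)
make_linear_trace <- function(slope_per_h, o2_start = 9, duration_s = 1200,
                              interval_s = 10, noise_sd = 0,
                              chamber_volume_l = 3.1, fish_mass_g = 100,
                              o2_saturation = NA_real_, ...) {
  time_s <- seq(0, duration_s, by = interval_s)
  o2 <- o2_start - slope_per_h * time_s / 3600
  if (noise_sd > 0) o2 <- o2 + rnorm(length(o2), 0, noise_sd)
  oxygen_trace("A1", "F1", time_s, o2,
               chamber_volume_l = chamber_volume_l,
               fish_mass_g = fish_mass_g,
               o2_saturation_mg_per_l = o2_saturation, ...)
}

# measurements table for a single fish on a simple linear trend
make_fish_measurements <- function(fish_id = "F1", group = "HL",
                                   days = seq(0, 70, by = 7),
                                   values, mass = 100) {
  switch_day <- 35
  phase1 <- days <= switch_day
  lev1 <- if (group == "HL") "HIGH" else "LOW"
  lev2 <- if (group == "HL") "LOW" else "HIGH"
  data.frame(fish_id = fish_id, group = group,
             event_index = seq_along(days) - 1L, day = days,
             days_in_phase = ifelse(phase1, days, days - switch_day),
             food_level = ifelse(phase1, lev1, lev2),
             rmr_observed = values, mass_g = mass,
             stringsAsFactors = FALSE)
}
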