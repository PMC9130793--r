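# metaplast

Tools for studying the **time course of metabolic plasticity** — how fast
fishes up- and downregulate their resting metabolic rate (RMR) when food
supply changes, and what that does to growth. The package is aimed at
ecophysiologists running intermittent-flow respirometry and crossover
feeding experiments, and at anyone who wants a fully synthetic, seeded
test bed for the associated longitudinal statistics.

## What it implements

**Respirometry.** Closed-chamber oxygen traces are trimmed (initial
settling discard, ~80 % air-saturation cutoff) and converted to
mass-specific oxygen uptake via

    MO2 = (V_r − V_f) · ΔO2 / M_f

with `V_r` the chamber water volume (L), `V_f = M_f/1000` the fish volume
(fish assumed neutrally buoyant), `ΔO2` the OLS uptake slope
(mg O2 L⁻¹ h⁻¹, consumption positive) and `M_f` the wet mass (g).

**Plasticity model.** RMR moves linearly toward an upper clamp at high
food and a lower clamp at low food, at weekly rates `rate_up` / `rate_down`
(optionally after a lag), and growth is linear conditional on food level
and RMR:

    dM/dt = c(F) + d(F) · RMR(t)

so mass trajectories are piecewise quadratic and any curvature in growth is
attributable to metabolic plasticity. Both are evaluated analytically (no
ODE stepping error).

**Synthetic experiments.** `generate_experiment()` emulates a 16-fish
crossover design (7 fish high→low food, 9 low→high, switch after five
weeks, 11 weekly measurement events) with individual baseline variation,
measurement noise, rare injected outliers, jittered measurement days and
prey-fish feeding records.

**Inference pipeline.** MAD-based running-median outlier cleaning with
linear interpolation; food-level-specific weekly slopes via a transparent
two-stage estimator or a linear mixed model with AR(1) residuals
(`nlme::lme`); percent-change and asymmetry-ratio contrasts; Welch tests;
penalized cubic-spline trajectory smoothing with GCV (`mgcv`); weekly food
intake as percent body mass.

## Worked example

```r
library(metaplast)

ds      <- generate_experiment(experiment_config(seed = 42))
cleaned <- clean_outliers(ds$measurements)
fit     <- fit_rmr_slopes(cleaned)          # two-stage estimator
print(fit)
#> Food-level-specific weekly slopes (two_stage, rmr):
#>   HIGH food: +0.0035 +/- 0.0010 (se) mg O2/g/h per week [n = 16 fish]
#>   LOW food: -0.0082 +/- 0.0011 (se) mg O2/g/h per week [n = 16 fish]

percent_change(coef(fit)["HIGH"], weeks = 5, baseline = 0.211)  # +8.2 %
percent_change(coef(fit)["LOW"],  weeks = 5, baseline = 0.211)  # -19.4 %
rate_ratio(abs(coef(fit)["LOW"]), coef(fit)["HIGH"])            # 2.37
```

The slopes are the weekly RMR drift at each food level (mg O2 g⁻¹ h⁻¹
wk⁻¹): this synthetic replicate was generated at +0.0038/−0.008, and the
pipeline recovers both, with downregulation about twice as fast as
upregulation — the asymmetry that makes rapid food drops costly long after
the switch.

A single respirometry assay, from trace to MO2:

```r
tr <- generate_o2_trace(0.209, fish_mass_g = 109, chamber_volume_l = 3.1,
                        noise_sd = 0.01, seed = 1)
estimate_mo2(tr)
#> MO2 estimate [synthetic]: 0.2079 mg O2/g/h (slope 7.578 mg/L/h, n = 49, r2 = 0.9991)
```

## Command line

A thin dispatcher (`run_cli()`, also installed as `exec/metaplast.R`)
exposes `generate`, `respirometry`, `simulate`, `analyze` and `recover`
subcommands over plain CSV files, e.g.

```sh
Rscript inst/exec/metaplast.R generate --outdir data --seed 42
Rscript inst/exec/metaplast.R analyze --measurements data/measurements.csv \
    --feedings data/feedings.csv --outdir results
```

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch, the package's headline
quantities: the deterministic five-week linear extrapolation of the pooled
baseline RMR at the low-food rate, and the mean recovered low-/high-food
weekly slopes across 200 replicate synthetic experiments pushed through
cleaning and the two-stage estimator. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/metabolic-plasticity.Rmd`) documents the
model assumptions, generator calibration, numerical choices and known
limitations.
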