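---
title: "Modelling the time course of metabolic plasticity under variable food supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the time course of metabolic plasticity under variable food supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaplast)
```

## The scientific problem

Many fishes upregulate their resting metabolic rate (RMR) when food is
abundant and downregulate it when food is scarce. If this plasticity is
slow relative to the pace of environmental change, an animal spends weeks
with a metabolic phenotype mismatched to its current food supply — paying
maintenance costs it cannot feed at low food, or lacking capacity at high
food. `metaplast` packages (i) a minimal quantitative model of this
process, (ii) the respirometry arithmetic needed to measure RMR in closed
chambers, (iii) a synthetic-data generator emulating a two-group crossover
feeding experiment, and (iv) the longitudinal statistics used to estimate
the plasticity rates from weekly measurements.

## The plasticity and growth model

RMR follows a clamped, rate-limited linear drift. Within a food-schedule
segment at level $F \in \{\mathrm{HIGH}, \mathrm{LOW}\}$, and after an
optional lag,

$$\frac{d\,\mathrm{RMR}}{dt} = \begin{cases}
 +\, r_{up}/7 & F = \mathrm{HIGH},\ \mathrm{RMR} < \mathrm{RMR}_{max}\\
 -\, r_{down}/7 & F = \mathrm{LOW},\ \mathrm{RMR} > \mathrm{RMR}_{min}\\
 0 & \text{at a clamp}
\end{cases}$$

with the weekly rates $r_{up}, r_{down}$ in mg O~2~ g^-1^ h^-1^ wk^-1^.
Growth is linear in time *conditional on* food level and RMR. The verbal
assumptions behind the conceptual model (high RMR speeds growth at high
food and speeds mass loss at low food; growth is linear for a fixed
combination of food and RMR) admit a one-line formalization, which we fix
as

$$\frac{dM}{dt} = c(F) + d(F)\,\mathrm{RMR}(t),$$

the simplest form in which all curvature of a growth trajectory is
attributable to metabolic plasticity. The context-dependence hypothesis
corresponds to the sign pattern $d(\mathrm{HIGH}) > 0 > d(\mathrm{LOW})$,
available as an enforced constraint in `growth_params(context_dependent =
TRUE)`; the default leaves signs free because the empirical
compensatory-growth pattern (previously starved fish out-growing
well-fed ones at high food) corresponds to $d(\mathrm{HIGH}) < 0$.

Both trajectories are evaluated **analytically**: RMR is piecewise linear
(knots at segment starts, lag ends and clamp crossings; a crossing occurs
at gap/rate days after the trend starts) and mass is piecewise quadratic,
integrated exactly by the trapezoid rule on the union of knots, schedule
boundaries and requested grid times — the rule is exact for a linear
integrand, so there is no discretization error to tune. Tests verify this
against brute-force dense stepping.

## Respirometry

Closed-chamber traces are processed per the standard protocol: discard the
first 120 s after valve closure (handling stress), truncate below 80 % air
saturation, fit an OLS slope of concentration on time in hours, negate it
so consumption is positive, and convert with
$\mathrm{MO}_2 = (V_r - V_f)\,\Delta O_2 / M_f$, where $V_f = M_f/1000$
assumes the fish has the density of water. Background respiration enters
as a chamber-level rate in mg O~2~ h^-1^ subtracted before mass-specific
conversion (default 0: measured blanks are typically negligible). No
temperature correction is applied — the intended use is small temperature
ranges. A rising trace returns a negative slope with a warning rather
than an error, so batch processing surfaces rather than hides bad assays.
With the studied mass range (66–141 g) in a 3.1 L chamber the fish-volume
fraction is 2.1–4.6 % — note this arithmetic is slightly narrower than the
2.5–5.5 % sometimes quoted for the same geometry, which would require a
smaller effective water volume; the volume is therefore a parameter, not a
constant.

## What the generator emulates — and what it does not

`experiment_config()` states the emulated world:

| parameter | default | basis |
|---|---|---|
| group sizes | 7 HL, 9 LH | crossover design after two escapes |
| events | 11 weekly, switch after 5 weeks | design |
| start mass | truncated N(109, 20²) on [66, 141] g | reported mean ± sd and range |
| prey mass | truncated N(6.7, 3.3²) on [1.6, 21.6] g | reported mean ± sd and range |
| feeds per week | 4 (high) / 1 (low), 96 % consumed | design |
| baseline RMR | 0.211, between-fish sd 0.04 | printed group means; sd back-derived from 95 % CIs (half-width ≈ 0.03, n 7–9) |
| measurement noise | sd 0.015 | residual scale consistent with the CIs |
| weekly rates | +0.0038 / −0.008 | fitted values |
| outliers | p = 0.017, shock sd 0.08 | 3 of 176 measurements flagged in the source analysis |
| day jitter | ±1 day | assays occasionally a day early/late |

Choices the source does not pin down, made once and documented here:

* **Clamps** default to [0.05, 0.5] mg O~2~ g^-1^ h^-1^ — wide enough to be
  non-binding over five weeks at the default rates, since the slope
  analysis presumes linear drift.
* **rmr0 truncation** at mean ± 2.5 sd, keeping baselines physiological
  without visibly distorting the Normal.
* **Growth calibration**: $c$(HIGH) = 2.3, $d$(HIGH) = −5,
  $c$(LOW) = 0.35, $d$(LOW) = −3 (g day^-1^; $d$ per unit RMR). These are
  package choices, not source values. They yield high-food growth near
  +1 % body mass day^-1^, slow low-food loss, weekly food intake near the
  reported percentages (≈21 % of body mass consumed per week at high food,
  ≈6 % at low), and — because $d(\mathrm{HIGH}) < 0$ — the
  compensatory-growth direction: the previously starved LH group, having
  downregulated its RMR, gains mass faster at high food than the HL group.
* **Mass weighing error**: multiplicative, cv 0.005 (≈0.5 g on a 110 g
  fish). The source states noise only for RMR; exactly noise-free masses
  would make mass-response model fits degenerate (zero residual), which no
  real dataset exhibits.

The generator does **not** emulate: tank effects, behavioural feeding
dynamics or prey escape, within-day diurnal metabolic cycles,
temperature drift, or any dependence of feeding capacity on metabolic
state. A green recovery test therefore establishes that the pipeline is
consistent and approximately unbiased *under the stated noise model*, not
that it is robust to structured noise the model omits.

## The estimation pipeline and its numerical choices

**Outlier cleaning.** Residuals are taken against a window-3 running
median (end windows shifted inward: the median of the first/last three
points, keeping endpoint residual scale comparable to the interior). A
point is flagged when its absolute residual exceeds $k \cdot 1.4826 \cdot
\mathrm{MAD}$ with $k = 3$. Two details matter numerically: the MAD is
computed over the *nonzero* residuals, because a self-inclusive window-3
median reproduces the central observation at roughly a third of positions
and the resulting point mass of zeros halves the scale estimate (causing
massive over-flagging); and the threshold is estimated once from the raw
series, then detection/replacement is iterated to a fixpoint, because
re-estimating the scale after each replacement lets the threshold collapse.
Flagged points are replaced by linear interpolation between the nearest
unflagged neighbours (endpoints take the nearest value). Exact functional
idempotence is not attainable for any detector that re-estimates its scale
from the data — cleaning removes the largest residuals, so a second pass
sees a slightly smaller MAD and may re-flag borderline points; the tests
assert bitwise preservation of unflagged values and near-idempotence
instead. With the default generator the detector's false-positive rate is
around 1–2 %; its sensitivity is intrinsically limited because many
injected shocks (sd 0.08) are smaller than any threshold that keeps false
positives rare — roughly, catching 80 % of N(0, 0.08) shocks needs a
threshold near 0.02, which measurement noise of sd 0.015 cannot support.
The acceptance suite states this bound honestly rather than tuning around
it.

**Slope estimation.** The primary estimator is deliberately transparent:
per fish and food phase, an OLS slope of the response on weeks-within-phase
(days since the last switch, divided by 7), then means within (group, food
level) and an n-weighted pool per food level, with the between-fish sd as
the dispersion. Phases with fewer than 3 points are dropped with a
warning. The mixed-model route fits cell-specific intercepts and weekly
slopes with a random intercept per fish and AR(1) residual correlation
(`nlme::lme`, REML); for the RMR response wet mass is available as a
centred covariate (default on, as in the published analysis). Note the
estimand: conditioning on mass yields *conditional* slopes, and in the
generator mass is an almost deterministic function of time, so the
covariate absorbs trend; like-for-like comparisons with the two-stage
(marginal) estimator therefore set `mass_covariate = FALSE`, under which
the two routes agree well within one group-level standard error.

Outlier cleaning costs a small attenuation of recovered rates (a few
percent toward zero): replaced endpoints take a neighbour's value, which
flattens per-fish regressions at their leverage points, and interpolation
across the switch-day kink shaves the peak. The uncleaned estimator is
exactly unbiased under the generator; the cleaned pipeline trades that for
robustness. The acceptance harness measures the recovered means over 200
replicates and checks them against the generating rates with a 20 %
bias bound.

**Percent change and asymmetry.** Five-week percent change is
$100\,(\mathrm{slope}\times\mathrm{weeks})/\mathrm{baseline}$ with the
baseline defaulting to the pooled, n-weighted initial mean
$(7 \times 0.209 + 9 \times 0.213)/16 = 0.21125$; reported unrounded.
With the printed rates this gives +9.0 % (high) and −18.9 % (low) over
five weeks — the latter is usually quoted rounded to 18 %. The asymmetry
ratio $r_{down}/r_{up} = 0.008/0.0038 \approx 2.105$, comfortably above
the conservative 1.8-fold bound quoted from unrounded fits.

**Smoothing.** Per group, a penalized cubic regression spline of the
response on day (`mgcv`, basis dimension 8), after centering each fish on
its own mean and restoring the group mean — a fixed-offset treatment of
individual intercepts that leaves the group-level shape untouched. The
smoothing parameter minimizes the GCV score; we use `mgcv`'s exact GCV
optimizer rather than a fixed 40-point grid search, the same criterion
with a strictly better optimum and no grid-resolution artefact. Shape
differences between groups are tested by an F-type comparison of residual
sums of squares between a shared smooth and group-specific smooths.
Pointwise 95 % bands cover the generator's true mean trajectory across
most of the grid on the default dataset, but these bands do not account
for smoothing bias, which concentrates at the switch-day kink of the true
(piecewise-linear) trajectory; over many replicate datasets the pointwise
coverage fraction averages below the nominal 95 %, dipping mainly near
the switch. A green coverage test on one dataset should not be read as a
universal coverage guarantee.

**Degenerate inputs.** Zero-variance time in the uptake regression is an
error; a constant O~2~ trace returns slope 0 with undefined $r^2$ (NA);
constant series produce no outlier flags; Welch's test on two zero-variance
samples returns $t = 0, p = 1$ when means agree and errors otherwise;
basis dimensions at or above the number of distinct days are rejected.

## Known limitations

* The growth coefficients $c(F), d(F)$ are calibration choices; only the
  sign structure and rough magnitudes are constrained by the emulated
  experiment.
* The outlier detector's sensitivity/false-positive trade-off is bounded
  by the stated shock and noise scales (see above); flag-for-flag
  agreement with any particular automated time-series routine is not a
  contract.
* Recovered rates carry a small cleaning-induced attenuation toward zero;
  applications where the rate magnitude (not just its sign and order) is
  critical should compare cleaned and uncleaned fits.
* The LMM route exists for fidelity to common practice; inference that
  matters should rest on the two-stage estimator, whose sampling behaviour
  is transparent.
* The simulator is deterministic and individual-level; it does not model
  energy budgets (assimilation, specific dynamic action, activity) or
  temperature dependence.
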