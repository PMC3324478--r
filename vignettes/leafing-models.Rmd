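---
title: "Spring leafing models driven by temperature and precipitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spring leafing models driven by temperature and precipitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoTP)
```

## The problem

The day of first leaf unfolding ("leafing") is the most climate-sensitive
stage of temperate plant phenology, and predicting it from daily weather is
a prerequisite for modelling carbon and water exchange under climate change.
Classical process models treat leafing as a purely thermal event: heat
(*forcing*) and sometimes cold (*chilling*) accumulate day by day until
critical sums are reached. That works well for trees in humid temperate
climates, but in semi-arid continental regions — steppe grasses especially —
leafing also waits for water. This package implements six daily-step
leafing models side by side, including a temperature–precipitation threshold
model (TP) in which leafing requires *both* a heat sum and a precipitation
sum to cross critical values, together with a least-RMSE simulated-annealing
calibrator, an odd/even-year validation protocol, and a synthetic weather
generator with known ground truth so every component can be tested without
observational data.

## The models

All models are pure functions of a daily weather series and a parameter
vector. Accumulation starts on a date `t0` (fixed by default: Jan 1 of the
leafing year for SW and TP, Sep 1 of the previous year for SM, PM and AM;
optionally searched as a day offset between Sep 1 and Jun 30), sums include
both `t0` and the candidate day, and the predicted day is the *first* day
the defining inequality holds (with `>=`, not `>`). Days are reported
relative to Jan 1 of the leafing year; a threshold met in the preceding
autumn yields values `<= 0`, which keeps prediction errors continuous across
New Year instead of wrapping. A threshold never met by Dec 31 is an
explicit "not reached" (`NA`); the fitting layer decides what that costs.

**Spring warming (SW).** Degree-days above a base temperature:
leafing at the first day with
$\sum_{t_0}^{y} \max(0, T_i - T_b) \ge F^*$.

**Temperature–precipitation (TP).** The SW thermal condition *and* a water
condition must both hold:
$$k_1 P_b + k_2 \sum_{t_0}^{y} R_i \ge P_{crit}
\quad\text{and}\quad
\sum_{t_0}^{y} \max(0, T_i - T_b) \ge F^*,$$
where $P_b$ is the previous calendar year's precipitation total, $R_i$
daily precipitation, $k_1, k_2$ the efficiencies of carried-over and
current-year water, and $P_{crit}$ the water threshold (mm). Equivalently
the prediction is the later of the first day each condition is met; with
$k_1 = k_2 = P_{crit} = 0$ TP reduces exactly to SW. The current-year sum
$\sum R_i$ starts at the same `t0` as the heat sum (a deliberate choice:
the two accumulators then share one window definition, and with the default
Jan 1 start this is simply "current-year precipitation before leafing").

**Sequential (SM).** Chilling accumulates from autumn at a triangular rate
(zero at `T_low` and `T_high`, 1 at the optimum `T_o`); when the chilling
state reaches `C*` (date `t1`, rest ends), sigmoid forcing
$v_a / (1 + e^{v_b (T + v_c)})$ accumulates until `F*`. Forcing is gated to
zero on days with `tmean <= T_b`, giving the fitted `T_b` a defined role
alongside the sigmoid constants. The sigmoid and triangle constants default
to the fixed literature values (`T_low, T_high, v_a, v_b, v_c` =
−3.4, 10.4, 28.4, −0.185, −18.4) and stay fixed in the default search
space.

**Parallel (PM).** Chilling and forcing accumulate simultaneously; each
day's sigmoid forcing is scaled by the bud competence
$K_m + (1 - K_m)\min(S_c/C^*, 1)$, computed from the chilling state
including the current day (competence 1 when `C* = 0`).

**Alternating (AM).** Chill days (`tmean < T_b`) and degree-days accumulate
in parallel; leafing requires at least `C*` chill days and a degree-day sum
reaching the moving requirement $a\,e^{b S_c}$. The two-constant
exponential form was chosen over three-constant variants because the
parameter set `{t0, T_b, C*, a, b}` with a large-scale `a` and a
small-magnitude rate `b` matches how the model family is reported.

**Growing season index (GSI).** Each day scores the product of three
indicators in $[0,1]$: an increasing ramp in daily minimum temperature
(−2 to 5 °C), a decreasing ramp in vapor pressure deficit (900 to 4100 Pa),
and an increasing ramp in photoperiod (36 000 to 39 600 s). The GSI is a
*trailing* 21-day mean of the product (shortened near Jan 1) — trailing
rather than centred, so the prediction is causal and uses no future
weather — and leafing is the first day it reaches a threshold, 0.5 by
default. The threshold is the one GSI parameter free by default in
calibration, since the source value is known to be too low for continental
sites and the optimum is species-dependent. VPD is computed from daily mean
temperature and daily mean relative humidity (a daytime VPD would need
sub-daily data, which the package deliberately does not handle); missing
humidity inside a GSI evaluation year is an error, never silently imputed.

### Derived meteorology

Saturation vapor pressure uses the Tetens formula
$e_s = 610.7 \cdot 10^{7.5T/(237.3+T)}$ Pa and
$\mathrm{VPD} = e_s(T)(1 - \mathrm{rh}/100)$. Photoperiod comes from the
sunrise equation with the Forsythe et al. (1995) revolution-angle
declination; no refraction or twilight correction is applied, which is
accurate to a few minutes — ample for a ramp spanning an hour of day
length. Polar latitudes (|lat| ≥ 66.5°) are rejected rather than
special-cased. One consequence worth knowing: because the declination
model carries the real orbit's eccentricity, annual day-length sums at
latitudes ±φ differ by about 1% (the sun spends more of the year at
northern declinations); the exact mirror identity is pointwise —
day(+φ, d) + day(−φ, d) = 24 h.

## Calibration and validation

Parameters are estimated by least RMSE (Eq. of the objective:
$\sqrt{\tfrac1n\sum_i (d_i - d_i^{obs})^2}$ over observation years). A year
in which a candidate parameter vector never reaches its thresholds
contributes a fixed `penalty_days` (default 400, i.e. worse than any real
miss) of absolute error — this keeps the objective finite everywhere and
pushes the search back toward parameter regions that produce dates.

The optimizer is Metropolis simulated annealing over the box-bounded free
parameters: uniform perturbations of 10% of each bound range, acceptance
probability $\min(1, e^{-\Delta/T})$, geometric cooling (factor 0.9) per
epoch, 200 steps per epoch for 50 epochs by default. The initial
temperature is auto-calibrated from 50 warm-up proposals so that roughly
80% of initial uphill moves would accept. The best-ever vector is
returned, the per-epoch best-RMSE trace is kept (and is non-increasing by
construction), and everything is reproducible from the mandatory integer
seed. An exhaustive grid search (`fit_grid`, at most 3 free parameters)
serves as an independent optimizer for verification; its ties break toward
smaller parameter values in declaration order so it is fully deterministic.

Default bounds cover the ranges these model families occupy in temperate
East Asian calibrations: `T_b` ∈ [0, 15] °C, `F*` ∈ [0, 1000] °C·day,
`k1, k2` ∈ [0, 1], `P_crit` ∈ [0, 60] mm, `C*` ∈ [0, 100] CU,
`K_m` ∈ [0, 1], `T_o` inside the fixed chilling triangle, `a` ∈ [1, 1000],
`b` ∈ [−0.2, 0.2], and a searched start date between Sep 1 of the previous
year and Jun 30 (day offsets −121 to 181).

Model skill is assessed by the odd/even-year protocol: odd calendar years
calibrate, even years validate, purely by parity (the two halves of a
25-year record are then 13 and 12 years, and the counts are reported rather
than forced equal). Reported statistics are RMSE, R² as the squared Pearson
correlation of predicted versus observed (so that the familiar regression
relation $F = R^2(n-2)/(1-R^2)$ holds, with df (1, n−2)), and that F.
R² deliberately uses correlation rather than $1 - SSE/SST$: it is then
shift-invariant, which separates "tracks interannual variation" (R²) from
"hits the date" (RMSE). When some years have no predicted date, RMSE uses
the penalty while R²/F are computed over the successfully predicted pairs
only (reported as `n_predicted`, `NA` with a warning below 3 pairs or for
constant vectors) — correlating penalty sentinels would be meaningless.

## The synthetic generator

`generate_weather()` draws a gap-free daily series from a configurable
climate; the defaults emulate a continental monsoon station: annual mean
4.5 °C with a seasonal half-range of 20.3 °C peaking at day 205 (January
around −15 °C, July around 22 °C), and about 514 mm of annual
precipitation with roughly 77% falling May–August (monthly wet-day
probabilities × a gamma amount with shape 0.7, scale 8 mm). Temperature
residuals are AR(1) with coefficient 0.7 and innovation sd 3.5 °C —
persistence matters because threshold-crossing dates are sensitive to runs
of warm or cold days, so i.i.d. noise would make recovery tests
unrealistically easy. `tmin` sits a half-normal offset (mean 5.5 °C) below
`tmean`; relative humidity is Gaussian (62 ± 12%) clipped to [5, 100].

What the generator does *not* emulate: the asymmetry of the real seasonal
cycle (a pure sinusoid cannot hit both a −18 °C January and a 22 °C July
around a 4.5 °C mean; the defaults favour the annual mean and range),
spatial correlation between stations, multi-day storm structure, or
humidity–precipitation coupling. Tests passing on synthetic data therefore
demonstrate correctness of the accumulation and calibration machinery and
recoverability of parameters under realistic persistence and noise — not
that any model is right for a particular real site.

`generate_leafing()` runs a known truth model over the usable years (the
first year only supplies carry-over weather), adds rounded Gaussian
observation noise, and clips to the calendar. If the truth model fails to
leaf in some year it refuses, naming the year, rather than emitting a
sentinel.

## Numerical and design notes

- All accumulators vectorize with `cumsum`; the calibrator additionally
  caches per-year weather windows once, so an annealing run evaluates pure
  numeric slices.
- Threshold comparisons are exact (`>=`); accumulated state at the day
  before a predicted date is strictly below the threshold.
- Warming monotonicity holds for SW and TP (adding heat can only advance
  them) and is checked as a property. It does *not* hold for AM in
  general: warming slows chill-day accumulation, so a chill gate
  (`C* > 0`) or a decaying requirement (`b < 0`) can legitimately delay AM
  leafing. The property test pins the regime where monotonicity is
  provable (`C* = 0`, `b >= 0`).
- Observed leafing days are validated against the real calendar (day 366
  only in leap years); weather series must be gap-free, which is checked on
  construction, never repaired.
- Test and acceptance problem sizes: 30-year single-station simulations
  for parameter recovery, two-year series for predictor/oracle checks, and
  reduced annealing schedules (20–30 epochs) in unit tests against the
  50-epoch default — sizes chosen so the whole suite exercises every code
  path on one CPU in a few minutes.

## Limitations

No gap-filling or quality control of weather input; no sub-daily data; no
photoperiod-driven models beyond GSI; no senescence; no pooled
multi-station calibration; no Bayesian uncertainty (the trace and seed
support restarts, not posteriors). Fitted parameters are calibration
constructs: different models (or bounds) yield different `T_b` for the
same plant, and the values should not be read as physiology.
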