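# passanova

Smoothing spline ANOVA (SSANOVA) models for daily physical-activity minutes
from two-arm wearable-accelerometer intervention studies.

## The problem

Wearable trackers (Fitbit-style) summarise each participant-day as minutes
spent sedentary and in light, fairly and very active intensity bands.  An
intervention trial then asks: how do the two arms' daily trajectories differ
over the intervention and follow-up periods, do scheduled group-workout days
produce discrete jumps on top of the smooth trend, and how uncertain are
those estimates?  Parametric growth curves are too rigid for such data;
`passanova` answers these questions nonparametrically, for biostatisticians
and exercise-science researchers analysing daily activity time series.

## The model

Each outcome is one observation per participant-day,

    y_i = z_i' beta + eta(t_i, g_i) + e_i,

where `t` is study day (scaled to [0,1]), `g` the arm, and `z` a 0/1
indicator of treatment-arm group-workout days whose coefficient `beta` is the
partial-spline jump.  The smooth surface is decomposed functional-ANOVA
style,

    eta(t, g) = eta0 + eta1(t) + eta2(g) + eta12(t, g),

with a constant, a smooth time main effect, a parametric ±1/2 group
contrast (a two-level factor has no smooth part) and a smooth time x group
interaction, identifiable through zero-mean side conditions.  Smooth terms
live in the cubic-spline reproducing-kernel space on [0,1] and are expanded
over kernel sections at a random subset of design points, so cohort-scale
fits stay cheap.

* Near-symmetric outcomes (sedentary, light-active minutes) are fitted by
  penalized least squares, `n^-1 sum (y_i - z_i beta - eta(x_i))^2 +
  lambda J(eta)`, after centering at the grand mean.
* Right-skewed outcomes (fairly/very-active minutes) use the Gamma family
  with log link, minimising the penalized negative log-likelihood
  `n^-1 sum (y_i exp(-eta_i) + eta_i)/sigma^2 + (lambda/2) J(eta)` by
  Newton/IRLS; zero minutes are handled by a recorded +0.5-minute offset
  (configurable).
* `lambda` is chosen by generalized cross-validation,
  `V(lambda) = n^-1 ||(I-A)y||^2 / (n^-1 tr(I-A))^2`, on a log grid with
  golden-section refinement (for Gamma fits, on the working data each
  Newton iteration).
* 95% Bayesian confidence bands come from the posterior covariance
  `sigma^2 M^-1` of the penalized fit, and intervention-window summaries
  report the mean daily group difference with CI, percent change vs
  baseline, and Cohen's d from participant-level window means.

Because raw cohorts of this kind are rarely shareable, the package includes
a synthetic cohort generator (`sim_config()`, `simulate_cohort()`) with the
same statistical structure — two arms over a 23-week window, an 8-week
intervention with weekly workout-day jumps, a mid-intervention effect peak
decaying through follow-up, Gaussian and Gamma outcome families, sporadic
missing days — so every stage is testable end to end.

## Worked example

```r
library(passanova)

sim <- simulate_cohort(sim_config(seed = 42))   # 33 + 31 participants, 161 days
fit <- pa_ssanova(sedentary_min ~ day + group, data = sim$records,
                  workout = "workout", family = "gaussian")
fit
#> Smoothing spline ANOVA fit (gaussian family)
#>   n = 9751 observations, groups PEER (+1/2) vs control (-1/2)
#>   lambda (GCV) = 1e-08, effective df = 17.66, dispersion = 8156
#>   workout-day coefficient beta = -44.5535
#>   notes: GCV minimiser at grid boundary log10(lambda) = -8.00

window_summary(fit, sim$records, "sedentary_min", 0:55)
#> sedentary_min (intervention window, days 0-55):
#>   mean daily difference -51.36 min/day (95% CI [-57.50, -45.22])
#>   -6.6% change vs baseline 778.12 min/day; Cohen's d = -4.63
```

The fit summary reports the GCV-selected smoothing parameter, the effective
degrees of freedom (trace of the smoother matrix), the error variance, and
the workout-day jump: on group-exercise days this simulated treatment arm
sits a further ~45 sedentary minutes below its smooth trend.  The window
summary averages the treatment-minus-control difference curve over the
intervention days: about 51 fewer sedentary minutes per day (the generator's
configured truth averages -53), a 6.6% reduction against the arm's first-week
baseline.  `predict_band()`, `ssanova_components()` and `group_difference()`
expose the fitted curves with 95% bands, the ANOVA components and the
difference curve; `plot(fit)` draws both arms with shaded bands.

The same pipeline runs from a shell:

```sh
inst/cli/pa-ssanova simulate --seed 7 --out cohort.csv
inst/cli/pa-ssanova fit --data cohort.csv --out results/
inst/cli/pa-ssanova report --results results/
```

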