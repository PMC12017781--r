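---
title: "Smoothing spline ANOVA for two-arm daily activity series"
author: "passanova"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing spline ANOVA for two-arm daily activity series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passanova)
```

## The model and its assumptions

`passanova` analyses daily activity-minute series from a two-arm
intervention study.  Each record is one participant-day with minutes in
four intensity categories; the model for one outcome is

$$y_i = z_i^\top\beta + \eta(t_i, g_i) + \epsilon_i,$$

with study day $t_i$ (affinely scaled to $[0,1]$ over the study window),
arm $g_i$, and a 0/1 workout-day indicator $z_i$ that is nonzero only for
treatment-arm records on scheduled group-exercise days.  Errors are taken
independent and identically distributed across records; within-participant
correlation and participant-level random effects are deliberately out of
scope (see Limitations).

The surface decomposes functional-ANOVA style,

$$\eta(t,g) = \eta_0 + \eta_1(t) + \eta_2(g) + \eta_{12}(t,g),$$

made identifiable by side conditions: $\eta_2$ and $\eta_{12}$ average to
zero over the two arms (enforced exactly by the $\pm 1/2$ contrast coding),
and $\eta_1$, $\eta_{12}$ integrate to zero over time (a property of the
kernel construction below).  A two-level factor admits no smooth main
effect, so $\eta_2$ is a single parametric contrast; the penalized terms
are the smooth time main effect and the smooth time $\times$ group
interaction.

Smooth terms live in the cubic-spline reproducing-kernel Hilbert space on
$[0,1]$ with kernel

$$K(s,t) = k_2(s)k_2(t) - k_4(|s-t|),$$

built from the scaled Bernoulli polynomials $k_1(x) = x - 1/2$,
$k_2 = (k_1^2 - 1/12)/2$, $k_4 = (k_1^4 - k_1^2/2 + 7/240)/24$; the
interaction kernel multiplies $K$ by the product of group contrasts.  The
unpenalized null space is spanned by $\{1, k_1(t), c(g), k_1(t)c(g)\}$.
Kernel sections integrate to zero and reproduce the roughness inner
product ($\int \partial_t^2 K(s,t)\,\partial_t^2 K(u,t)\,dt = K(s,u)$,
since $\partial_t^2 K(s,t) = k_2(s) - k_2(|s-t|)$); both facts are checked
numerically in the test suite.

Two outcome families are supported, matching the empirical shapes of the
four categories:

* **Gaussian** (sedentary, light-active minutes; near-symmetric): the
  outcome is centered at its pooled grand mean (restored on prediction)
  and the coefficients minimise
  $n^{-1}\sum_i (y_i - z_i\beta - \eta(x_i))^2 + \lambda J(\eta)$.
  Dispersion is $\mathrm{RSS}/(n - \mathrm{tr}\,A)$.
* **Gamma with log link** (fairly/very-active minutes; right-skewed):
  coefficients minimise the penalized negative log-likelihood
  $n^{-1}\sum_i (y_i e^{-\eta_i} + \eta_i)/\sigma^2 + (\lambda/2)J(\eta)$,
  which under the log link is the Gamma negative log-likelihood up to
  constants.  The dispersion $\sigma^2$ (reciprocal shape) enters only as
  a scale, so it is estimated post hoc by the Pearson statistic
  $\sum ((y_i-\hat\mu_i)/\hat\mu_i)^2 / (n - \mathrm{tr}\,A)$ rather than
  profiled.

## Computation

Fitted functions are expanded over kernel sections anchored at a random
subset of $q = \min(n_u, \lceil 10\,n^{2/9}\rceil + 30)$ *distinct* design
points ($n_u$ the number of distinct $(t,g)$ pairs), sampled without
replacement under a recorded seed.  Full $n \times n$ solves are $O(n^3)$;
the subset basis makes a 10,000-record cohort fit in well under a second
while leaving small problems exact ($q = n$).  Distinctness matters:
participants share days, and duplicated anchors would make the penalty
Gram singular.

With unpenalized block $S$ (null basis plus the $z$ column), cross-kernel
block $Q$ and penalty Gram $R$ (rescaled to unit mean diagonal so the
$\lambda$ grid is comparable across datasets), the normal equations are

$$\begin{pmatrix} S^\top W S & S^\top W Q\\ Q^\top W S & Q^\top W Q + n\lambda R\end{pmatrix}
\begin{pmatrix} d \\ c\end{pmatrix} = \begin{pmatrix} S^\top W y\\ Q^\top W y\end{pmatrix},$$

solved by Cholesky factorisation.  $R$ carries a $10^{-10}$ ridge on its
diagonal (duplicated design rows are routine); the assembled system gets
an additional ridge only if the factorisation actually fails, scaled to
the data cross-product so that the $\lambda \to \infty$ parametric limit
is not perturbed.

$\lambda$ minimises the GCV score
$V(\lambda) = n^{-1}\|W^{1/2}(I-A)y\|^2 / (n^{-1}\mathrm{tr}(I-A))^2$
over 21 grid points, $\log_{10}\lambda \in [-8, 2]$, followed by
golden-section refinement to $10^{-3}$ in $\log_{10}\lambda$; a minimiser
at the grid edge is reported in the fit log.  Per-term scales
$\theta = (1, 1)$ are fixed by default — a single smoothing parameter, the
standard choice here — with an optional two-sweep alternating
$\theta$/$\lambda$ GCV refinement (`pa_control(theta_refine = TRUE)`).

The Gamma fit is Newton iteration on the penalized likelihood: weights
$w_i = y_i e^{-\eta_i}$, working response
$\tilde y_i = \eta_i + (y_i e^{-\eta_i} - 1)/w_i$, each step solving the
weighted penalized least-squares subproblem, with up to 10 step-halvings
so the objective never increases.  $\lambda$ is re-selected by GCV on the
working data each outer iteration and frozen after iteration 5 so the
objective being minimised stops moving; convergence is a relative
objective change below $10^{-6}$ (at most 30 outer iterations; a
non-converged fit is returned flagged, and the band functions refuse it).
The iteration starts at the constant $\eta = \log \bar y$, which is safe
for any positive data.

Zero minutes (common in the fairly/very-active categories, excluded by the
Gamma support) are handled by adding 0.5 min to every response, recorded
in the fit and removed again on the response scale; `drop` and `none`
policies are available.  The offset choice is visible in all reported
minutes-scale quantities for near-zero baselines and is therefore always
carried in the fit object.

## Inference

Interpreting the penalized fit as a posterior mean under a Gaussian-process
prior, the coefficient posterior covariance is $\hat\sigma^2 M^{-1}$ with
$M$ the (weighted) penalized system matrix, so a curve evaluation row
$e(x)$ has variance $\hat\sigma^2 e(x)^\top M^{-1} e(x)$.  95% bands are
$\hat\eta \pm 1.96\,\mathrm{sd}$ on the linear-predictor scale,
exponentiated (and offset-corrected) to minutes for Gamma fits.  Such
bands are known to achieve roughly nominal coverage *averaged across the
function* rather than pointwise everywhere — the test suite checks exactly
that property (average-over-grid coverage within $[0.90, 0.99]$ over 50
replicates).

The treatment-minus-control difference curve is
$2(\eta_2 + \eta_{12}(t))$ under the $\pm 1/2$ coding, excluding
workout-day jumps; for Gamma fits it is reported on both the log and
minutes scales (delta method).  Window summaries average this curve over
the intervention or follow-up days, with the CI from the posterior
covariance of that average, and attach:

* **percent change** $= 100\,\Delta/\mathrm{baseline}$, rounded to one
  decimal.  The baseline is the treatment arm's first-week (days 0–6) mean
  of the raw outcome by default, overridable in the study config — the
  natural "baseline" is study-specific and therefore explicit.
* **Cohen's d** from participant-level window means (not day-level
  records), to avoid pseudo-replication.  Note that with no
  between-participant heterogeneity in the generator (see below),
  participant means are very precise and standardized effects come out
  much larger than typical real-cohort values; d is reported for its
  definition, not calibrated against any published value.

## The synthetic cohort generator

`sim_config()` defaults describe the study design the package targets: 33
treatment and 31 control participants, 161 days (23 weeks, the first 8 of
them the intervention; both counts are configurable), one weekly workout
day during the intervention, 5% sporadic missingness.  Outcome baselines are
795 (sedentary), 200 (light), 7.43 (fairly) and 1.09 (very active)
min/day; the light-active baseline is a free choice (not a published
value), as are the noise scales (Gaussian sd 90/60 min, Gamma shapes
1.5/1.2) — values a daily Fitbit series plausibly shows.  Peak treatment
effects (−66, +15, +0.26, +0.19 min/day) are set so the
intervention-window average differences land near −53, +12, +0.21 and
+0.15 min/day.

The treatment effect follows the unit-peak profile
$b(d) = (d/m)e^{1-d/m}$ with $m$ = mid-intervention: zero at entry, peak
at $m$, decaying to under 20% of peak by the end of a 23-week window —
the "improves during intervention, wanes during follow-up" shape.  Both
arms share a gentle sinusoidal drift (±2%).  Workout-day jumps are
additive minutes for Gaussian outcomes and multiplicative
($e^{\beta}$, default 1.5) for Gamma outcomes, matching each family's
natural scale.  Gaussian draws are truncated to $[0, 1440]$ and the four
categories are proportionally rescaled on the rare days their sum exceeds
1440 minutes.

What the generator does *not* emulate: participant-level random effects,
serial correlation within participants, device wear-time artefacts, or
intraday structure.  Passing recovery and calibration tests on these
cohorts therefore validates the estimator under its own i.i.d.
assumptions; it does not demonstrate robustness to the correlation
structure real wearable data certainly have.

## Numerical and test-design choices

* Problem sizes: recovery simulations use 600–800 records; band
  calibration uses 50 replicates of $n = 800$; the null-specificity sweep
  runs ten 10+10-participant cohorts; the attenuation check uses one
  500-per-arm cohort, since the configured fairly/very-active effects
  (~0.2 min/day against day-level noise of several minutes) cannot be
  ordered between windows reliably at 33+31 participants.
* The workout-jump recovery experiments oversample workout days so the
  jump coefficient is well replicated, and the Gamma jump check judges
  the median of five seeded replicate fits (per-fit sampling sd ~0.05 on
  the log scale) against its recovery band.
* Interpolation-limit checks ($\lambda \to 0$, full basis) use small
  equispaced designs: forming normal equations squares the kernel's
  condition number, and beyond a dozen points the smallest kernel
  eigenvalues fall below double precision.
* The null-interaction check asserts pointwise 95% credible coverage of
  zero on at least 90% of grid days (in 8/10 null replicates), the
  calibrated form of "the interaction is indistinguishable from zero":
  a sup-statistic compared against a median posterior sd would fail even
  for an exactly calibrated posterior, because the sup is attained where
  the posterior sd is largest (the domain edges).
* Ties and degenerate inputs: duplicated $(t, g)$ rows are expected and
  handled by the ridge; single-arm data are rejected (the interaction is
  unidentifiable); the workout term is dropped with a logged note when
  fewer than 3 workout-day observations exist; prediction outside the
  fitted day window is an error rather than an extrapolation.

## Known limitations

Within-participant correlation is ignored, so posterior sds are
anti-conservative for strongly autocorrelated participants; random-effect
or correlation-model extensions would be the natural next step.  The
Gamma fit freezes $\lambda$ after five performance-oriented iterations —
a pragmatic convergence guarantee, not a joint optimum.  Percent-change
baselines and Cohen's d conventions vary across studies; both are
explicit knobs here rather than attempts to match any particular report.
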