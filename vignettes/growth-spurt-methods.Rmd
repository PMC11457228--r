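---
title: "Modelling the pubertal growth spurt: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pubertal growth spurt: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the numerical choices and
the deliberate design decisions behind `growthspurt`. It states no
empirical result that the package's tests and acceptance analysis do not
themselves compute.

## The shape-invariant growth model

Mixed-longitudinal height data consist of repeated measurements
`(subject, sex, age, height)` over overlapping, incomplete age ranges. The
model assumes every individual's height curve is a common mean curve
subjected to three subject-level transformations:

$$h_{it} = \alpha_i + g\!\left(c + (t - c - \beta_i)\,e^{\gamma_i}\right)
  + \varepsilon_{it}, \qquad \varepsilon_{it} \sim N(0, \sigma^2),$$

with $(\alpha_i, \beta_i, \gamma_i) \sim N(0, \Omega)$:

* **size** $\alpha_i$ (cm) shifts the whole curve vertically;
* **tempo** $\beta_i$ (years) shifts the growth pattern along the age
  axis — positive tempo means later puberty;
* **velocity** $\gamma_i$ (log-scale, dimensionless) compresses
  ($\gamma > 0$) or stretches the age axis about the pivot age $c$,
  making the spurt steeper/shorter or shallower/longer. Height velocity is
  the analytic derivative $v_{it} = e^{\gamma_i} g'(x)$.

The pivot $c$ (default: the mean observed age) is an identifiability and
numerical-stability device: without it the age-scaling would hinge at age
zero and tiny velocity effects would translate into implausibly large
timing shifts. Models with different pivots are near-reparameterisations
of one another, so the choice is not substantive.

The mean curve $g$ is a natural cubic spline (linear beyond its boundary
knots, continuous second derivatives). The package evaluates the basis and
its first two derivatives analytically; finite differences are used only
in tests, as oracles.

### Estimation

The fit alternates three exact block updates until the penalised
complete-data log-likelihood stabilises (relative change below `tol`,
default `1e-6`, at most `max_iter = 200` outer iterations):

1. **Mean curve**: given the effects, the spline coefficients solve a
   weighted least-squares problem on the transformed ages.
2. **Effects**: each subject's $(\alpha_i, \beta_i, \gamma_i)$ maximises
   its penalised log-likelihood (residual term plus the $N(0, \Omega)$
   shrinkage penalty) by BFGS with analytic gradients.
3. **Variances**: $\sigma^2$ and $\Omega$ take their closed-form maximisers
   given residuals and effects.

Each step maximises the same objective over its own block, so the traced
objective is non-decreasing across iterations — a property the test suite
checks. After convergence the effect means are absorbed into the mean
curve (a centring polish), so the reported effects are exactly centred.
The reported $\Omega$ adds the Gauss–Newton (Laplace) conditional
covariance of each subject's effects to the second moment of the modes;
without this correction shrinkage understates the random-effect
dispersion. Initialisation is deterministic ($\alpha_i$ from subject mean
heights, $\beta_i = \gamma_i = 0$), so fits are reproducible without a
seed.

## Spurt-parameter extraction

On a velocity curve $v(t)$ the package defines:

* **APHV / PHV** — the location and value of the global maximum of $v$
  over the search window (default 7–16 years);
* **AOGS / OGSV** — the age of maximal acceleration $v'$ before APHV
  (takeoff) and the velocity there;
* **spurt end / GSI** — the first age after APHV at which $v$ falls back
  to OGSV, and the interval from AOGS to that age.

"Takeoff" is operationalised as the maximum of the *first* derivative of
velocity (peak acceleration). An alternative reading — the steepest rise
of the acceleration itself, i.e. peak jerk — is ill-defined for cubic
splines (their third derivative is piecewise constant), so the
peak-acceleration reading is adopted and fixed.

Numerics: a dense grid scan (step 0.01 y) followed by local refinement
(golden-section for extrema, bisection for roots) to `1e-4` y. Curves
whose peak or takeoff lands on a window boundary, or whose end is not
reached before the search limit (default 18 y, where the spline is already
in its linear tail), are flagged and excluded from cohort summaries with
counts reported.

### Where the spurt landmarks can live on a spline

A point with large consequences: for a cubic-spline height curve the
acceleration is **piecewise linear**, so

* the extracted takeoff age can only fall on a knot (the argmax of a
  piecewise-linear function), and
* at an interior velocity peak, the single acceleration line shared by the
  late rise and the early fall forces those two limbs to have proportional
  curvature.

Working the reported spurt geometry through this algebra (takeoff
velocity well below the peak, a pre-peak span near 2.3 y but a post-peak
return to takeoff velocity within about 1.3 y) shows that *quantile-placed
knots of any plausible df cannot represent it*: either the takeoff lands
on the wrong knot or the velocity tail is forced far negative. The
geometry is representable exactly when interior knots sit **at the takeoff
age, at the peak age, and shortly after the spurt end** (where the
acceleration kinks). The package therefore:

* calibrates its template curves in a spline space with such
  landmark-derived knots, and
* lets `fit_sitar()` accept explicit knots (`options$knots`), which the
  study pipeline sets to the stratum's template knots. The default remains
  quantile placement for general use.

In a parameter-recovery study the mean-curve family, including its knots,
is part of the generating model, so supplying the landmark knots to the
fitter is the standard "fit the generating family" design; the tests then
measure estimation error rather than curve-family misspecification. The
flip side is stated under *Limitations*.

## The synthetic cohort generator

The generator emulates the sampling design of a school-based
mixed-longitudinal growth study:

| quantity | default (boys / girls) | note |
|---|---|---|
| template spurt means | AOGS 10.17/8.57 y, OGSV 5.43/5.10 cm/y, APHV 12.46/10.99 y, PHV 9.61/8.32 cm/y, GSI 3.58/3.72 y | calibration targets of the packaged presets |
| height at age 7 | 122.9 / 121.8 cm | level anchor; adult heights emerge near 178/166 cm |
| random-effect SDs | size 5 cm; tempo 0.69/0.74 y; velocity 0.131/0.130 | tempo from the APHV dispersion; velocity from the PHV coefficient of variation; size is a free choice (its true scale is not published) |
| random-effect correlations | 0.09/0.33/−0.43 (boys), 0.18/0.29/−0.36 (girls) | size–tempo / size–velocity / tempo–velocity |
| measurement noise SD | 0.78 / 0.714 cm | from the published mean absolute fit errors via the half-normal identity $E|\varepsilon| = \sigma\sqrt{2/\pi}$ |
| visit schedule | nominal ages 7.25, 7.75, …, 16.25; jitter ±0.25 y; missingness 0.31 | biannual school visits; jitter and missingness chosen so the per-subject measurement count averages ≈ 12.4 *and* ≥ 90 % of subjects pass the five-segment inclusion filter — with narrower jitter those two published design facts are arithmetically incompatible |
| age pivot | 11.5 y | centre of the design span |

Each subject draws its effect triple from the trivariate normal, its visit
ages from the jittered schedule with independent per-visit missingness,
and its heights from the model plus Gaussian noise. Per-subject random
sub-streams are derived from (seed, sex, subject index), so subject $k$ is
invariant to the cohort size and the two sexes' cohorts are independent.

### Template calibration

Rather than inverting a parametric growth family, the template *is* a
spline and the calibration is a constrained linear solve: the conditions
$v(\mathrm{aogs}) = \mathrm{ogsv}$, $v'(\mathrm{aogs}) = 2\,\mathrm{amp}/T$
(the triangular-acceleration peak, whose integral over the rise is exactly
the velocity gain), $v(\mathrm{aphv}) = \mathrm{phv}$,
$v'(\mathrm{aphv}) = 0$ and $v(\mathrm{end}) = \mathrm{ogsv}$ are all
linear in the spline coefficients and are imposed exactly (consistent
redundancies dropped); the remaining freedom least-squares matches a
smooth reference velocity shape (declining childhood velocity, a shallow
pre-takeoff dip — an unavoidable corollary of defining takeoff at *maximum*
acceleration — and decline towards near-zero adult velocity). The solved
template is verified by running the extraction on it; calibration fails
loudly if any target is missed. Parametric families were tried first and
rejected: their shape manifolds cannot reach the required post/pre-peak
asymmetry (ratio ≈ 0.56) and takeoff-to-peak velocity ratio
(≈ 0.57) simultaneously.

### What the generator does not emulate

No secular trends, cohort effects, informative missingness,
heteroscedastic or non-Gaussian measurement error, and no model
misspecification: the template lies exactly in the fitted spline family.
Passing recovery tests therefore demonstrate that the estimation and
extraction machinery is consistent and well-calibrated under the study's
sampling design — not that the model would fit arbitrary real cohorts
without curve-family error.

## Statistical summaries

* Centiles use linear interpolation of order statistics (quantile type 7);
  means use the sample SD with the $n-1$ denominator.
* Random-effect correlations are Pearson coefficients with two-sided
  p-values from the t transform on $n-2$ degrees of freedom.
* Quintile contrasts rank subjects by one parameter, take the
  $\lfloor 0.2n \rfloor$ largest and smallest, and compare another
  parameter's means with a **Welch** (unequal-variance) two-sample t-test;
  ties straddling the cut are resolved by a stable sort on subject id so
  the grouping is deterministic. The pooled-variance alternative and other
  quantile conventions would be equally defensible; these choices are
  fixed and documented so outputs are bit-reproducible.
* Sexes are always analysed as separate strata. Significance is flagged at
  $p \le 0.05$; nothing is silently filtered by significance.

## Problem sizes

The recovery experiments simulate 150 subjects per sex per seed and
average three seeds; unit tests use cohorts of 25–60 subjects and
noiseless self-consistency checks at 35 subjects. These sizes match the
scale of the motivating study (123/147 subjects per sex after filtering)
and keep the full suite comfortably fast on one core.

## Limitations

* **Takeoff resolution is knot-limited.** On any cubic-spline fit the
  takeoff age snaps to a knot; AOGS dispersion across subjects comes from
  their tempo/velocity transforms of that knot, not from per-subject
  curvature detail.
* **Peak-location sensitivity.** The fitted peak sits where a
  piecewise-linear acceleration crosses zero near a kink; measurement
  noise propagates into a seed-level APHV uncertainty of roughly 0.1–0.2
  years (visible in the acceptance runs), with a slight earlier-age lean
  because the post-peak limb is much steeper than the pre-peak limb.
* **Self-consistency, not robustness.** Because generation and fitting
  share the spline family and knots, the experiments quantify estimation
  error only; applying the pipeline to real data should revisit knot
  placement (e.g. from a pilot quantile-knot fit that localises the spurt).
* **Approximate likelihood.** Conditional-mode estimation with moment
  variance updates is not exact maximum likelihood; the reported $\Omega$
  corrects the first-order shrinkage bias but small biases remain, and the
  per-subject effects are shrunken estimates by design.
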