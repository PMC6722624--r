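---
title: "Modelling joint-angle-specific torque curves and functional H:Q ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling joint-angle-specific torque curves and functional H:Q ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Isokinetic knee testing produces, per athlete, thousands of torque samples
indexed by joint angle, for four action–mode combinations: concentric and
eccentric knee extension and flexion. The quantities of scientific interest
are smooth population torque–angle curves and, derived from them, the
joint-angle-specific functional hamstring-to-quadriceps ratios — eccentric
hamstrings over concentric quadriceps for extension, concentric hamstrings
over eccentric quadriceps for flexion — together with the angles at which
the extension ratio crosses the point of equality (1.0) and the locations
of the flexion ratio's extrema.

Two features of the data drive the model choice. First, torque is strongly
nonlinear in angle, with peak locations that differ between muscle groups
and contraction modes, so a parametric curve family would be restrictive.
Second, samples are nested within athletes: consecutive observations share
an athlete's overall strength level and curve shape, so treating them as
independent would both understate uncertainty about the population curve
and conflate within- and between-athlete variation.

## The hierarchical GAM

For one action–mode dataset, torque $y_{ij}$ of athlete $i$ at angle
$x_{ij}$ is modelled as

$$y_{ij} = \beta_0 + f(x_{ij}) + b_{0i} + f_i(x_{ij}) + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathcal N(0, \sigma^2),$$

with a single common smoother $f$ — all athletes share one functional
shape — plus athlete-level deviations in two forms: a random intercept
$b_{0i} \sim \mathcal N(0, \sigma_b^2)$ and a smooth shape deviation
$f_i$ pooled toward zero, whose basis coefficients share one variance
$\tau^2_{\text{ind}}$ across athletes. Each of the four action–mode
datasets is fitted independently; the ratios pair the per-action
posteriors afterwards.

### P-splines and their mixed-model form

Both $f$ and $f_i$ are P-splines: cubic B-spline bases over the angle
domain with uniformly spaced interior knots, boundary knots replicated
degree-plus-one times, evaluated by the Cox–de Boor recursion, and
penalized by the second-order difference matrix $S = D^\top D$. The
penalty is eigendecomposed, $S = U \Lambda U^\top$: the two zero
eigenvectors span the unpenalized (constant + near-linear) part kept as
fixed-effect columns $X_0 = B\,U_0$, and the remaining directions become
columns $Z = B\,U_+ \Lambda_+^{-1/2}$ on which an i.i.d. zero-mean
Gaussian coefficient prior is exactly the original wiggliness penalty.
Smoothing thus reduces to estimating variance components, and the whole
model is a conjugate Gaussian linear mixed model.

The per-athlete deviations $f_i$ use only the penalized columns of a
smaller basis ($K_{\text{ind}} = 6$): their constant component is already
carried by $b_{0i}$, and leaving the deviations fully penalized keeps them
shrunk toward the common shape.

### Basis dimension

The population basis default is $K = 12$ (knot spacing of 10° over
0–90°). We initially considered $K = 10$, but the recovery studies in the
test suite showed that with ~13° knot spacing the smoother cannot resolve
torque curves whose curvature changes quickly around a narrow peak (the
eccentric-flexion curve peaks sharply near 55°); the resulting mid-range
smoothing bias is small in absolute terms (~1–2 N·m) but material against
a population credible band of similar width, depressing band coverage.
$K = 12$ removes that resolution bias at negligible cost; results should
be reported with $K$ stated, and it remains a configuration knob.

### Priors and sampling

"Uninformative" priors are operationalized as inverse-gamma(0.001, 0.001)
on every variance component ($\sigma^2$, $\sigma_b^2$, $\tau^2_{\text{pop}}$,
$\tau^2_{\text{ind}}$) and $\mathcal N(0, 10^6)$ on the unpenalized fixed
coefficients; all are configurable. Because the model is fully conjugate,
it is fitted by a blocked Gibbs sampler: one joint multivariate-normal
update of all coefficients via the penalized normal equations (a single
Cholesky factorization per iteration), then inverse-gamma updates of each
variance. Every update is exact, so there is no acceptance tuning, and
given a seed the sampler is reproducible bit for bit. Defaults are 4
chains of 2,000 iterations with 1,000 warmup; the studies in the test
suite run shorter chains (400–800 iterations) because the conjugate
sampler mixes essentially instantly — the joint coefficient update leaves
almost no autocorrelation — and those problem sizes are stated below.

Convergence is checked with split-$\widehat R$ per scalar parameter
(flagged above 1.01) and a bulk effective sample size computed with
Geyer's initial positive-sequence truncation.

The global intercept, the null-space columns and the athlete indicators
overlap (the constant direction appears in all three); the proper priors
make the joint update well-posed, the fitted curve and all reported
quantities depend only on identified sums, and the joint Gaussian update
mixes over the ridge directions exactly.

## Preprocessing

Two rules reduce raw dynamometer exports to model-ready series.

- **Truly isokinetic filtering.** Only samples recorded at the target
  velocity carry the intended load. The filter keeps samples with
  $\bigl|\,|v| - 60\,\bigr| \le$ `tolerance_dps`; the absolute value
  covers both movement directions, whose raw velocities have opposite
  signs. The default tolerance is ±6 deg/s (10% of the target): the
  criterion itself prescribes no band, and 10% is the conventional
  engineering default. The tolerance is configurable.
- **Best repetition.** "Best" is operationalized as the repetition with
  the greatest peak torque within each athlete–action–mode group, ties
  broken by the lowest repetition number. Exactly one repetition
  contributes per group.

Ratios are always paired on the anatomical knee-flexion angle; extension
results are *displayed* on the rescaled extension-progress axis
(`90 - angle`, 0 at the start of the action) only. Angles are treated as
continuous throughout — no binning.

## Posterior outputs

`posterior_curve()` evaluates $\beta_0 + f(\cdot)$ per retained draw on an
angle grid, marginalizing athlete effects at their zero mean; a flag adds
new-athlete intercept and shape variability for individual-level
prediction bands. The reported band is the equal-tailed 95% percentile
interval (order statistics of draws; no HPD), matching common Bayesian
reporting practice.

Grids are restricted to the angle range actually observed after filtering:
the smoothers refuse to extrapolate, and near the range-of-motion ends no
truly isokinetic data exist, so the pipeline reports curves on the
observed support (about 5–85° under the default generator).

`functional_ratio()` divides numerator by denominator draws
iteration-by-iteration. The two fits are independent, so pairing draw $s$
of one posterior with draw $s$ of the other is a valid Monte-Carlo sample
of the ratio posterior. Grid points where the denominator's posterior-mean
torque falls below 1 N·m (configurable) are masked to prevent ratio
blow-up. Crossings of the equality level use linear interpolation between
adjacent grid points straddling the level, with exact hits reported once;
extrema are sign changes of first differences, plateaus reporting their
midpoint, endpoints excluded.

WAIC is computed from the stored pointwise log-likelihood matrix as
$-2(\text{lppd} - p_{\text{waic}})$ with a log-sum-exp-guarded lppd and
the sample-variance penalty; model comparisons report the elpd difference
and its standard error $\sqrt{n \,\mathrm{var}(\Delta_i)}$. The compared
pair is the full model versus the variant without individual smooth
deviations — the natural question being whether athletes differ in curve
*shape* beyond overall strength level.

## The synthetic study

No dynamometer data are distributed, so the generator reproduces the
statistical structure the model assumes, with known truth: 30 athletes ×
4 action–modes × 5 repetitions, angle-sampled at 1°, trapezoidal velocity
profiles (ramp, constant 60 deg/s, ramp), and torque built as population
curve + athlete intercept (SD 8 N·m) + athlete smooth deviation + repetition
shortfall + noise (SD 6 N·m).

Key generator choices, and why:

- **Population curves** are skewed Gaussian bumps with a baseline floor
  (value at the peak angle equals the peak parameter exactly). The default
  parameters were calibrated once, against the qualitative curve features
  the analysis is meant to detect, before any model fitting: the true
  extension ratio crosses equality at exactly 40° of extension progress;
  the true flexion ratio is bimodal (peaks near 20° and 80°, trough ≈0.54
  near 55°) and never reaches 1.0; the eccentric-flexion torque curve
  peaks at exactly 55°; all curves stay positive and physiologically
  scaled (peaks 114–211 N·m). These planted features are what the recovery
  tests score against.
- **Athlete smooth deviations** are drawn from the same penalized B-spline
  family the model fits (the well-specified case), with a Fourier-basis
  switch (`dev_family = "fourier"`) for deliberate misspecification
  studies. The deviation scale is parameterized as the root-mean-square
  curve amplitude in N·m (default 6), converted internally to the
  coefficient-scale SD — an amplitude is interpretable; a raw coefficient
  SD is not.
- **Repetition effects** are nonpositive effort shortfalls:
  `sd_rep * (u - max u)` within each group, so the best repetition attains
  the athlete's capacity exactly. Zero-mean offsets would make the
  best-repetition curve systematically higher than the population curve by
  the expected maximum of five draws, leaving "recover the population
  curve" ill-posed; with shortfalls the planted curve is the truth of what
  the pipeline estimates, and the true best repetition is still simply the
  largest offset.
- **Ramp fraction** defaults to 5% of the range of motion per end. At
  60 deg/s a dynamometer reaches the target velocity within a few degrees,
  and the planted flexion-ratio peak at 80° must lie inside the truly
  isokinetic window to be estimable at all; 5% leaves data on ~5–85°.
  During ramps, systematic torque is attenuated in proportion to the
  velocity shortfall, so unfiltered acceleration-phase samples are biased —
  the filtering step has a real job.

What the generator does **not** emulate: autocorrelated residuals along
the movement (the model likewise assumes i.i.d. noise — see limitations),
fatigue across repetitions, velocity-overshoot oscillations, or any
musculoskeletal mechanics. Passing recovery tests therefore demonstrates
that the estimation machinery is correct under its own assumptions, not
that those assumptions hold for any particular dynamometer.

## Numerical choices

- Penalty eigenvalues below `max(lambda) * 1e-10` are treated as zero; a
  null-space dimension different from the difference order is an error.
- The right domain endpoint is assigned to the last knot interval so the
  partition of unity holds on the closed domain.
- Fit serialization writes draws with 17 significant digits and reloads
  them with `strtod`-based parsing, giving bit-exact round trips; the
  pointwise log-likelihood is recomputed on reload with the same
  matrix-vector product the sampler used, so it too is bit-exact.
- Degenerate inputs: a single athlete drops all random effects with a
  warning; an athlete with fewer than $K_{\text{ind}} + 2$ observations
  triggers a weak-identification warning, not an error; an emptied
  athlete–action–mode group after filtering is omitted with a warning.
- Ties in best-repetition selection go to the lowest repetition number;
  exact grid hits in crossing detection are reported once.

## Test and study sizes

The bundled validation studies use the full default study conditions
(30 athletes, 4 action–modes) with shortened chains, sized so the whole
suite runs in minutes: a 20-replicate recovery sweep at 400 iterations per
fit (population-curve RMSE, 95%-band coverage, ratio crossing and peak
recovery), a 20-replicate WAIC discrimination study (800 iterations for
the null arm, where Monte-Carlo error in the elpd difference must be small
against its standard error), and unit-level oracle checks (direct
penalized least squares, generalized-ridge conditional means, straight-loop
WAIC, brute-force crossing bracketing, `splines::splineDesign`).

## Known limitations

- Residuals are modelled i.i.d., though consecutive samples along a
  movement are plausibly autocorrelated; with autocorrelation the
  population bands would be somewhat anticonservative. An autoregressive
  residual structure is a natural extension the conjugate sampler could
  accommodate.
- Best-repetition selection maximizes a noisy peak, so a shortfall
  repetition occasionally wins; this induces a small downward shift of the
  estimated curves, most visible for broad, flat torque profiles where
  repetition peaks are hardest to discriminate (the eccentric-extension
  mode in the synthetic study). It is a property of the best-repetition
  procedure, not of the model.
- Band coverage is evaluated for the population curve; bands for a *new
  athlete's* curve require the `include_individual` flag and are wider.
- Whether published per-action credible bands correspond to population- or
  individual-level uncertainty is often unstated in applied work; the
  package reports population-level bands by default and exposes the flag
  rather than guessing.
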