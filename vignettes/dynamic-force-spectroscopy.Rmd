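---
title: "Dynamic force spectroscopy with dfspec: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic force spectroscopy with dfspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfspec)
```

This vignette is the package's account of the science it implements: the
kinetic and mechanical models, what the synthetic-data generator does and
does not emulate, the tunable parameters with their units and defaults,
the numerical choices, and the design decisions taken where the
literature leaves the procedure open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The measurement

In an AFM single-molecule force spectroscopy experiment a ligand is
tethered to the cantilever tip through a flexible PEG linker and the
receptor is immobilised on the support. Each cycle approaches the tip
until a preset contact force is reached and then retracts it at constant
velocity $v$. If a bond formed, the retraction stretches the tether,
bending the cantilever towards the surface; at some force the bond
ruptures and the cantilever snaps back to its baseline. Deflection is
converted to force by Hooke's law, $F = k_c\,\Delta z$. The signature of
a *specific* unbinding event is therefore a nonlinear attractive ramp —
the tether's force–extension curve — ending in an abrupt jump whose
height is the rupture force, located at a tip–surface separation
comparable to the tether length rather than at the contact zone.

## Bond kinetics: the single-energy-barrier model

The bound state escapes over one barrier whose rate grows exponentially
with the applied force,

$$k(F) = k_{\mathrm{off}}\exp\!\left(\frac{F x_\beta}{k_B T}\right),$$

with $k_{\mathrm{off}}$ the zero-force dissociation rate (s⁻¹) and
$x_\beta$ the barrier width (nm), the projection of the transition state
along the pulling direction. At constant loading rate $r$ (pN/s) this
implies a closed-form rupture-force density (implemented in
`rupture_force_density()`, with CDF and inverse-CDF sampler companions)
whose mode is the most probable unbinding force

$$F^*(r) = \frac{k_B T}{x_\beta}\,
  \ln\!\frac{x_\beta\, r}{k_B T\, k_{\mathrm{off}}},$$

clamped at zero below the threshold rate $k_BT\,k_{\mathrm{off}}/x_\beta$
because rupture forces are magnitudes and in the sub-threshold regime the
density's mode sits at zero. $F^*$ rises linearly in $\ln r$ with slope
$k_BT/x_\beta$, which is what the dynamic force spectrum fits. The
thermal energy defaults to $T = 298$ K (room temperature), i.e.
$k_BT = 4.114$ pN·nm; the temperature is exposed everywhere a context is
accepted.

These closed forms serve a second role: they are the *oracle* for the
stochastic simulator. The simulator never uses them to generate data —
it integrates the hazard step by step — so agreement between the two is
a genuine cross-check (the Kolmogorov–Smirnov blocks in the test suite
and acceptance script).

## Tether mechanics

PEG linkers are classically described by the freely-jointed chain, used
here in its Langevin form

$$x(F) = L_c\left(\coth\frac{F l_k}{k_BT} - \frac{k_BT}{F l_k}\right),$$

with contour length $L_c$ and Kuhn length $l_k$. The defaults
$L_c = 10$ nm and $l_k = 0.7$ nm emulate PEG18/PEG27 chemistry with
short peptide spacers; they are modelling choices, not measured
constants — the instrument literature for this preparation publishes no
tether mechanics — and they place specific ruptures at 5–15 nm
separation, clearly beyond contact adhesion. During retraction the piezo
displacement is shared between tether extension and cantilever
deflection, $d = x(F) + F/k_c$; `solve_force_at_separation()` solves
this monotone balance by safeguarded bisection on $F \in [0, 500]$ pN to
a 10⁻⁹ nm separation residual (both terms increase in $F$, so the root
is unique and bracketing is robust). The tangent stiffness $dF/dx$ is
the quantity read off a curve at rupture as $k_{\mathrm{PEG}}$; its
zero-force limit is $3k_BT/(L_c l_k)$. Enthalpic (two-state) PEG
elasticity and tip-shape contact mechanics are out of scope; the tether
model sits behind three functions so an alternative (e.g. a worm-like
chain) could be slotted in.

## The synthetic-data generator

`simulate_ensemble()` emulates the study conditions the package is
designed around: six log-spaced pulling velocities spanning 50–8000 nm/s
(realised loading rates of order 10²–10⁵ pN/s), 1000 curves per
velocity, a 30 pN/nm (0.03 N/m) cantilever, a 13% per-curve
specific-binding probability, and room temperature. Where no measured
value exists the defaults are realistic fixture choices, fixed once:
5 pN Gaussian force noise per sample, 0.2 nm piezo sampling, a 5%
probability of a nonspecific contact-adhesion artifact (a triangular
attractive spike within 5 nm of contact, 20–80 pN peak — deliberately
something for the separation-window filter to reject), zero baseline
tilt (the analysis estimates tilt regardless and is tested against
tilted baselines), and a 100 pN approach force limit.

A bound retraction is generated by stepping the piezo outward on the
exact tether + cantilever force profile and rupturing with per-step
hazard $1 - \exp(-k(F)\,\Delta t)$, $\Delta t = \text{step}/v$. Stepping
the hazard (rather than inverting an event time under a constant-rate
assumption) honours the nonlinear FJC loading; at the default step,
$k(F)\Delta t \ll 1$ over the relevant force range. A tether that never
ruptures inside the sampled range is force-ruptured at the last solvable
point and flagged `truncated`. Ensembles are deterministic given the
seed, with one RNG sub-stream per curve so curves are independent and
reproducible individually. Sign convention: attractive forces are
negative in stored traces; events report positive rupture magnitudes.

What the generator does *not* emulate — and hence what passing tests do
not certify on real data: cantilever ringing and hydrodynamic drag,
1/f drift beyond a linear tilt, multiple simultaneous tethers,
heterogeneous or multi-barrier bonds, and thermal-noise spring-constant
calibration (spring constants are taken as given metadata).

## Event detection

`detect_events()` operationalises the classical visual criteria with
explicit, configurable thresholds (`detection_settings()`); the source
literature publishes none, so these were calibrated on synthetic
ensembles and are documented as such:

* baseline: robust linear fit over the far-from-surface 25% of the
  retract; noise scale $\sigma$ = 1.4826 × MAD of the residuals;
* smoothing: 5-point moving average;
* a candidate is a contiguous excursion below $-3\sigma$ lasting at
  least 8 points, whose force builds monotonically (negative fitted
  slope) towards the minimum, and which returns to baseline within 3
  points of the minimum (plus half a smoothing window, since the
  smoothed trace lags the jump);
* the rupture force is the height of the jump back to the *local*
  post-rupture baseline — measuring the jump rather than the absolute
  excursion cancels the baseline-extrapolation error, and is also how
  the readout is classically described;
* the loading stiffness is the least-squares slope of force against the
  piezo axis over the final 8 points. That slope *is* the series
  stiffness $dF/dd = k_{\mathrm{eff}}$, from which
  $k_{\mathrm{PEG}} = (k_{\mathrm{eff}}^{-1} - k_c^{-1})^{-1}$ follows.
  Fitting against the tip–sample separation directly (the textbook
  phrasing "slope at rupture") is mathematically equivalent but
  statistically ill-conditioned: the same force noise enters both axes,
  correlated, and near rupture the true separation advance per step
  shrinks by $k_{\mathrm{eff}}/k_{\mathrm{PEG}}$, so the fitted slope
  frequently flips sign. The piezo axis is noise-free; the series
  relation is exact.
* a candidate is accepted as *specific* iff its rupture separation
  (piezo + deflection) falls in the window [5 nm, 1.5 $L_c$], which
  rejects contact-zone adhesion — the software analogue of the
  linker-only control experiments.

All candidates are recorded; where a curve yields several accepted
events the one at the largest separation is the specific event for
ensemble statistics (single tether: the farthest rupture). Binding
probability counts curves, not events.

Per-event rupture forces carry the irreducible single-sample noise
$\sigma$, so ensemble tests require unbiasedness and a median absolute
error within 1.5$\sigma$ rather than a hard per-event bound.

## Ensemble statistics

The rupture-force distribution per velocity is estimated as the mean of
unit-area Gaussian kernels, one per event, with width equal to the
originating curve's baseline $\sigma$ (a fixed bandwidth can be forced).
This measurement-uncertainty smoothing resolves the mode better than a
histogram; the pdf is renormalised to unit trapezoidal area on its grid
(0.1 pN spacing, span [0, max + 4$\sigma$]). $F^*$ is the centre of a
Gaussian fitted (Levenberg–Marquardt) to the main mode within ±2 initial
widths of the grid argmax, the initial width taken from the half-maximum
span; a failed fit falls back to the argmax with a flag. Smoothing a
skewed distribution shifts its mode slightly downward (about 1 pN at
5 pN kernels for typical parameters); the mode-consistency tests budget
for this. The reported $F^*$ standard error is the larger of the fit
covariance term and the sampling term width/$\sqrt{n}$. Control pdfs are
not subtracted from specific pdfs (no such subtraction is part of the
procedure); any display normalisation of pdfs to a binding probability
is a plotting concern, not part of the statistic.

Group comparisons use Student's two-tailed equal-variance $t$ test
(Welch behind a flag), labelled `*`, `**`, `***` at $p$ < 0.05, 0.01,
0.001.

## The Bell–Evans fit

`fit_bell_evans()` regresses $F^*$ on $\ln r$ — the classical procedure,
not a maximum-likelihood fit on raw forces — weighting each velocity
group by the effective variance
$w_i^{-1} = \mathrm{se}_i^2 + b^2(\mathrm{sd}_{r,i}/r_i)^2$, which is
how a spread of loading rates within a group is "considered" in the
fit; because the slope $b$ enters the weights the fit is iterated to
10⁻⁸ convergence on the slope. With all uncertainties zero the fit
reduces to ordinary least squares and round-trips noiseless data to
machine precision. Per-velocity points are fitted (the default; fitting
per-event points instead is possible by constructing the points table
directly). The parameter transform is $x_\beta = k_BT/b$ and
$k_{\mathrm{off}} = b^{-1}\exp(-a/b)$; 95% intervals use the delta
method with a $t_{n-2}$ quantile, on the log scale for
$k_{\mathrm{off}}$ so the interval respects positivity. The covariance
is the usual residual-rescaled weighted-regression covariance, so the
band self-calibrates even if the supplied uncertainties are off by a
common factor. $k_{\mathrm{off}}$, an extrapolation of the intercept to
zero force, is always the noisier parameter; the recovery tests assert
its relative interval exceeds $x_\beta$'s.

`confidence_band()` gives the pointwise 95% band from the
intercept/slope covariance (undefined below 3 points, where there are
no residual degrees of freedom). The coverage simulation in the test
suite and acceptance script exercises the band construction directly:
replicate spectra draw per-velocity $F^*$ values as closed-form truth
plus noise of known scale, with jittered loading rates and realistic
within-group spreads. Folding the full detection chain into each of 200
replicates would instead test the (separately audited) kernel-smoothing
mode shift, which is common to all velocities and absorbed by the
intercept.

## Problem sizes and runtimes

The validation suite uses ensembles sized to make its assertions sharp
while staying interactive: 2000-curve noiseless ensembles at 0.02 nm
stepping for the sampler/oracle Kolmogorov–Smirnov comparisons
(distance < 0.05 at three parameter sets), 1000-curve noisy ensembles
for the detection and binding-probability audits, six velocities × 300
bound curves for parameter recovery (tolerances ±15% on $x_\beta$,
factor two on $k_{\mathrm{off}}$, set by pilot simulation), and 200
replicates for band coverage (95% ± 4%). The full suite runs in well
under a minute on one CPU.

## Known limitations

* Single-barrier, single-bond kinetics only: no Dudko–Hummer–Szabo
  $\nu \ne 1$ corrections, catch bonds, or mixture populations.
* The detector assumes one dominant tether per curve; overlapping
  ruptures closer than the smoothing window merge.
* $k_{\mathrm{PEG}}$ from an 8-point secant underestimates the tangent
  stiffness where the tether stiffens quickly; the induced loading-rate
  bias is a few percent in the logarithm and lands in the intercept
  ($k_{\mathrm{off}}$), not the slope ($x_\beta$).
* Curve files are a plain-text dialect; vendor instrument formats
  (JPK/Igor/Bruker) need external conversion, for which the dialect is
  documented in `read_force_curve()` and the packaged example.
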