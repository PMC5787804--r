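# dfspec — single-molecule dynamic force spectroscopy

`dfspec` analyses atomic force microscopy (AFM) single-molecule force
spectroscopy experiments in which a receptor–ligand bond, coupled to the
cantilever tip through a flexible PEG tether, is loaded until it
ruptures. It is written for biophysicists who record force–distance
curves over a range of pulling velocities and want to go from raw curves
to kinetic parameters of the probed bond, with every step of the chain
testable against ground truth.

The pipeline implements the classical analysis used for peptide–peptide
interactions such as the Orai N-terminus / loop2 fragments of the CRAC
channel complex:

1. **Curve processing** — cantilever deflection is converted to force by
   Hooke's law, *F = k·Δz*; the retraction baseline (offset, tilt, noise
   σ) is estimated robustly; unbinding events are detected as a
   nonlinear attractive ramp (stretching of the PEG tether) terminated
   by an abrupt jump back to baseline. Each event yields the rupture
   force, the tether stiffness at rupture *k*<sub>PEG</sub>, the series
   stiffness *k*<sub>eff</sub> = (*k*<sub>PEG</sub>⁻¹ + *k*<sub>c</sub>⁻¹)⁻¹
   and the loading rate *r = k*<sub>eff</sub>·*v*.
2. **Ensemble statistics** — binding probability (fraction of curves
   with a specific event), an empirical probability density of rupture
   forces (mean of unit-area Gaussian kernels, widths set by the
   measurement noise), and the most probable unbinding force *F\** from
   a Gaussian fit to the density's main mode. Two-sample comparisons use
   Student's two-tailed *t* test with the usual star convention.
3. **Dynamic force spectrum** — under the Bell–Evans single-energy-
   barrier model the escape rate grows exponentially with force,
   *k(F) = k*<sub>off</sub> exp(*F x*<sub>β</sub>/*k*<sub>B</sub>*T*), so

   *F\**(r) = (*k*<sub>B</sub>*T*/*x*<sub>β</sub>) · ln( *x*<sub>β</sub> *r* / (*k*<sub>B</sub>*T* *k*<sub>off</sub>) )

   rises linearly with ln *r*. A weighted linear fit of *F\** against
   ln *r* (effective-variance weights folding in the spread of loading
   rates) recovers the barrier width *x*<sub>β</sub> and the zero-force
   dissociation rate *k*<sub>off</sub>, with delta-method 95% confidence
   intervals and pointwise confidence bands.

Because raw AFM archives are rarely deposited, the package ships a
physics-based generator of synthetic curve ensembles — Bell rupture
kinetics stepped along the exact freely-jointed-chain tether + cantilever
force profile, Gaussian instrument noise, baseline tilt, nonspecific
contact adhesion, configurable binding probability — so the whole
pipeline can be validated end to end.

## Worked example

Simulate a six-velocity experiment (50–8000 nm/s, ~300 bound curves per
velocity, 30 pN/nm cantilever, 5 pN noise) with known kinetics
(*k*<sub>off</sub> = 0.1 s⁻¹, *x*<sub>β</sub> = 0.5 nm), then run the
full analysis:

```r
library(dfspec)
cfg <- simulation_config(curves_per_velocity = 300, p_bind = 1, seed = 101)
experiment <- run_dfs_experiment(cfg)
print(experiment$summaries[[5]])
print(experiment$fit)
```

```
<velocity_summary> v = 2899 nm/s: 300 curves, 298 events, BP 0.993 +/- 0.005
  F* = 91.22 +/- 0.70 pN; loading rate 6.39e+04 +/- 1.26e+04 pN/s
<bell_evans_fit> F* = intercept + slope * ln(r)
  slope 8.338 pN, intercept -1.751 pN, 6 points
  x_beta = 0.4934 nm  [0.4557, 0.5311] (95% CI)
  k_off  = 0.148 1/s [0.07423, 0.295]
  reduced chi-square 0.233
```

At 2899 nm/s nearly every curve shows a specific event; the most
probable unbinding force there is 91.2 pN at a mean loading rate of
6.4×10⁴ pN/s. The fitted slope of *F\** versus ln *r* (8.34 pN, i.e.
*k*<sub>B</sub>*T*/*x*<sub>β</sub>) gives *x*<sub>β</sub> = 0.493 nm —
within 1.5% of the generating 0.5 nm — and the extrapolated intercept
gives *k*<sub>off</sub> = 0.15 s⁻¹, within the (always wider) factor-two
uncertainty typical of the extrapolated parameter; both 95% intervals
cover the truth.

The same chain is available from the shell (see `exec/dfspec`):

```sh
dfspec run-all --config inst/extdata/example_config.yaml --out out/
```

which writes `curves/` (TSV curve files + `manifest.json`),
`events.csv`, `summary.csv`, `summary_pdfs.csv` and `fit.json`, each
stamped with the configuration hash and seed. An annotated example
curve file lives at `inst/extdata/example_curve.tsv`; attractive forces
are stored negative in curve files, events tables store positive
rupture magnitudes.

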