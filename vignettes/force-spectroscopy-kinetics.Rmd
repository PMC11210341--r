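---
title: "Models and methods: antibody-receptor kinetics from AFM force spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: antibody-receptor kinetics from AFM force spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(forcespec)
```

This vignette documents the models behind `forcespec`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test-suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The measurement and its data model

In a cell-surface SMFS experiment, a single antibody sits at the end of a
~6 nm PEG linker on the AFM tip. Each cycle records piezo position versus
cantilever force: approach, optional constant-contact dwell, retract. If a
bond formed during contact, the retract trace shows a nonlinear tensile
stretch — linker plus cell-membrane tether — ending in one or two abrupt
force drops (ruptures). `forcespec` represents one cycle as a `force_curve`
(z in nm increasing away from the surface; force in pN, tensile positive;
per-sample segment labels) and stores curves in a bit-exact TSV dialect with
a JSON manifest per curve set, so fixtures are portable and diffable.
Proprietary vendor formats are out of scope.

## 2. Dissociation: Bell–Evans under a force ramp

A bond with zero-force off-rate `koff` (s⁻¹) and barrier width `xbeta` (nm)
loaded at rate `r` (pN/s) ruptures with density `p(F | r)` given in
`?bell_density`; its mode is linear in `ln r`. Thermal energy defaults to
`KBT_ROOM = 4.114` pN·nm (298 K) and is an argument everywhere.

`fit_bell_ml()` maximises the exact per-event likelihood in
`(log koff, log xbeta)`. Three aspects deserve explanation:

* **Measurement-error convolution** (`convolve_error`). Each detected force
  carries a Gaussian error of a few pN (the post-rupture cantilever
  fluctuation, recorded per event). Fitting raw forces treats that
  broadening as Bell-intrinsic and inflates `koff` several-fold on recovery
  fixtures; convolving each event's density with its error (21-node
  Gauss–Hermite quadrature) removes the bias. The low-level default is
  `FALSE` (both modes are tested and exposed because published analyses do
  not always state which was used); the pipeline wrapper
  `analyze_experiment()` enables it.
* **Gate-window truncation** (`window`). Single-bond events are selected as
  `mu1 ± 2*sigma1` of the bimodal decomposition. A likelihood unaware of
  that truncation is biased; passing the gate as `window` renormalises the
  density over the retained mass (including the convolution's edge effect,
  via the same quadrature). This also absorbs the detector's inability to
  see ruptures below the SNR threshold, since the gate's lower edge sits
  above it.
* **Optimisation and errors.** Nelder–Mead first, then a BFGS polish with
  observed-information standard errors reported on the log10 scale (errors
  in the exponent, i.e. normal on log k). The simplex stage matters: far
  from the optimum the windowed likelihood has a flat underflow plateau and
  a degenerate ridge (`xbeta → 0` mimics a uniform density on the window)
  onto which a pure quasi-Newton start can jump.

Events enter this fit with a per-event loading rate `r = v · keff`, where
`keff = (1/kc + 1/kl)⁻¹` is the series compliance of cantilever and
molecule. `kl` is the analytic derivative, at the rupture force, of a
Marko–Siggia worm-like chain fitted to the pre-rupture stretch
(`fit_wlc()`); when that fit cannot run, a local linear slope over the last
20 samples is used and flagged. On membrane-dominated, nearly linear
stretches the individual contour and persistence lengths are weakly
identified, but the local stiffness — the only quantity propagated — is well
determined.

## 3. Bivalency: the uncorrelated two-bond Markov chain

Two Fab arms form mechanically uncoupled bonds. The chain leaves state 2 at
rate `2·koff·exp(s·F·xβ/kBT)` — `s = 1/2` when the arms share load
(default), `s = 1` when each bears the full load; the published wording
("no mechanical coupling") does not decide this, so both variants are
implemented and neither is asserted as the original intent — and leaves
state 1 at the single-bond rate. Two independent implementations exist and
are cross-checked in the tests:

* `sample_double_bond_forces()` inverts the piecewise-analytic cumulative
  hazards transition by transition (exact; no time stepping);
* `predict_double_bond()` integrates the master equation on a force grid
  with `deSolve::lsoda` (rtol 1e-10; state-2 occupancy analytic; density
  renormalised for grid truncation, mode refined by quadratic
  interpolation).

At zero force the lifetime is `Exp(2koff) + Exp(koff)` with mean
`1.5/koff`, which is the entire content of the whole-molecule reduction
`two_bond_off_rate()`: `koff_2bonds = koff/1.5`. Lifetimes are `1/koff`.

## 4. Association: dwell-time kinetics and the effective concentration

`fit_dwell_curve()` fits `P(t) = A·(1 − exp(−(t − t0)/τ))` (t0 ≥ 0, weights
= inverse binomial variance with a +0.5/n stabiliser; an unweighted mode
exists for parity with a plain least-squares reading). `on_rate()` closes
the model with `kon = 1/(τ·Ceff)` — the unique dimensionally consistent
pseudo-first-order inversion given the hemisphere effective concentration
`Ceff = 1/(N_A·(2/3)π r_eff³)`; with the 6 nm linker and 4 nm half-antibody
defaults, `Ceff ≈ 7.9e-4` M. The second-bond rate is unimolecular:
`kon2 = 1/τ₂` from the double-bond fraction, no concentration conversion.

Dwell times are measured from the curves themselves: contact extent on
approach and retract (compressive-force cluster adjacent to the surface,
threshold 2× baseline sd, with the contact ramp extrapolated to its
zero-force crossing so the threshold does not clip the extent) divided by
the sweep velocity, plus any explicit dwell segment. Short dwells are
reached with fast sweeps, long ones with explicit dwell segments — the same
trade the instrument protocol makes by varying the sweep rate.

## 5. Event detection and classification

Candidates are sharp downward steps of a width-5 running-median trace;
each candidate is anchored at the steepest unsmoothed single-sample drop and
accepted iff (a) the mean of a short pre-window minus the post-window median
is ≥ `snr_threshold` × the local noise sd (MAD of a 50-sample post-rupture
window), (b) the smoothed trace falls by the same threshold within the drop
span, and (c) the smoothed peak clears the threshold against the global
baseline sd. Default `snr_threshold = 2`. Comparing window means rather
than single samples is what keeps the false-positive rate negligible at so
low a threshold; forces are always reported from unsmoothed data, so
noiseless fixtures are recovered exactly. Ties between maxima sharing a
drop span keep the later sample.

Curves are classified `none` / `single` / `double_simultaneous` /
`double_sequential` (two events within or beyond a 5 nm simultaneity
window; the window is a package choice, the published analysis does not
quantify "simultaneous"). Curves with more than two events are classified
by their last two, with a warning — a documented package rule. For kinetic
analysis only each curve's final rupture is used (a sequential pair's final
rupture is a genuine single-remaining-bond event); binding probability
counts a curve once regardless.

Two bonds that break within the detector's resolution merge into one step,
so double-bond counting for the association analysis also counts
single-drop curves whose force exceeds `mu1 + 2·sigma1` — the high-force
(second-Gaussian) population. The event-count classifier is unchanged by
this; the cutoff only feeds the double-bond fraction.

## 6. The synthetic-data generator

`simulation_config()` defaults are the study conditions: cantilever
10 pN/nm, 2000 samples per curve, 3000 nm z-range, force noise 3 pN,
sweep velocities giving loading rates of order 50–5000 pN/s, truths
koff = 0.23 s⁻¹, xβ = 1.23 nm, A = 0.13, τ = 26.3 ms (so that
kon ≈ 4.8 × 10⁴ M⁻¹s⁻¹ at the hemisphere Ceff), kon2 = 17 s⁻¹.
Where the sources give no value, the following were chosen once as
realistic and are documented here:

* molecular compliance = Marko–Siggia WLC (contour 6 nm, persistence
  0.38 nm, typical PEG) in series with a linear membrane spring of
  0.35 pN/nm — this puts `keff` near 0.34 pN/nm (r ≈ 1000 pN/s at
  3000 nm/s) and ~140 nm of membrane stretch at 50 pN, consistent with the
  soft, hundreds-of-nm membrane tethers seen on living cells;
* cell contact stiffness 2 pN/nm (≈25 nm indentation at the 50 pN
  setpoint), which admits dwell times down to ~6 ms at fast sweeps;
* saturated double-bond probability `double_sat = 0.04` of all curves
  (~30% of bound curves), shaped as its own pseudo-first-order law
  `P₂(t) = double_sat·(1 − e^{−kon2·t})` in the marginal over curves —
  the form the downstream fit presumes; making it conditional on binding
  would turn the observed fraction into a product of two saturating curves
  and decouple `1/τ₂` from `kon2`.

Ruptures are planted by inverting the cumulative Bell hazard accumulated
along the actual simulated force trajectory (not at a fixed nominal rate),
with the two-bond chain switching to the single-linker elastic branch after
the first rupture. Ground truth (class, true forces and positions,
instantaneous loading rates) lives in a `truth` sidecar that the curve
writer never serialises, so analysis code cannot read it even by accident.
Identical config + seed gives bit-identical output.

What the generator does **not** emulate — and what recovery tests therefore
cannot certify on real data: instrument drift, hydrodynamic drag and
cantilever ringing, nonspecific tip–surface adhesion, heterogeneous
receptor density and cell-to-cell variability, multiple (>2) simultaneous
tethers, and force-dependent association.

## 7. Problem sizes and numerical conventions

The test-suite sizes were chosen so that each stochastic check is decisive
at its tolerance: Bell-recovery coverage uses 50 replicates of 2000 events
at four loading rates; the two-bond Monte-Carlo consistency checks use 10⁵
lifetimes and 10⁴ rupture forces (Kolmogorov–Smirnov distance < 0.02);
association recovery uses 1000 curves per dwell point across nine dwell
times spanning 6 ms–0.35 s; the end-to-end CLI run uses three conditions of
eight 80-curve cells, since the quantities it asserts are closed-form
identities that hold at any size. Numerical conventions: kBT = 4.114 pN·nm;
xβ reported in Å in tables (nm internally); log10-scale standard errors;
Clopper–Pearson binomial intervals; grid/step and tolerance values are
recorded in the relevant function documentation.

## 8. Known limitations

* The Bell–Evans single-barrier model only (no Dudko–Hummer–Szabo or
  Friddle–Noy variants), matching the analysis it re-implements.
* Mixture means of overlapping, skewed rupture-force populations
  underestimate the upper mode; the bimodal fit is used for locating and
  gating populations, not for reporting double-bond forces (the master
  equation does that).
* `kon2` is the statistically weakest output: double-bond events are a few
  per cent of curves, so its error bars are wide unless thousands of curves
  per dwell point are measured.
* With a single sweep velocity the loading-rate span is narrow and `xbeta`
  is weakly constrained; `fit_bell_ml()` warns when the span is below a
  factor of five.
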