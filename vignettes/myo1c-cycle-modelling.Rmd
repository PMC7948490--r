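---
title: "Modelling the acto-myosin-1C ATPase cycle: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the acto-myosin-1C ATPase cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myo1ckin)
```

# The model

Human myosin-1C is a single-headed class I myosin whose three splice
isoforms differ only in an N-terminal extension (NTE) of 0, 16 or 35
residues. The extension tunes ADP release, the working stroke and load
sensitivity, and thereby the motor's duty ratio and power output. This
package models the chemistry and the mechanics of the tail-truncated
constructs with two NTE variants (`myo1c0`, `myo1c35`) and lets both be
confronted with stopped-flow, steady-state ATPase and in vitro motility
data.

## The nine-state reaction scheme

The ATPase cycle is a minimal scheme over nine species. `A` is F-actin,
`M` myosin-1C, `T` ATP, `D` ADP; the prime marks the closed conformation
of the nucleotide pocket:

```
AM' <=> AM <=> AMT <=> AM'T <=> M'T + A
 |       ^                       |
 |       | k5 (ADP release)      | hydrolysis (lumped, irreversible)
 |       AM'D <= AM'DPi <=> M'DPi + A
 M + A <=> AM (rigor binding)
```

Each reaction step has a forward and a backward rate constant
(`rate_constant_set()`); bimolecular constants are in 1/(uM s),
unimolecular in 1/s, and concentrations in uM throughout. Conversions
happen only at I/O boundaries (actin affinities are reported in nM,
matching convention).

Modelling assumptions, all deliberate:

* **Clamped ligands.** ATP, ADP, Pi and actin concentrations are held
  constant (`ligand_conditions()`), the pseudo-first-order approximation
  appropriate for stopped-flow mixes and steady-state assays run in
  ligand excess. Long incubations that visibly deplete ATP (hours of an
  NADH-coupled assay) are outside the model.
* **Lumped, irreversible hydrolysis.** The detached hydrolysis step is
  a single rate `khyd` representing the sum of forward and reverse
  hydrolysis rates, which is exactly what a tryptophan-fluorescence
  relaxation measures; no separate reverse rate is introduced.
* **No actin-free turnover path.** The scheme has no M + ATP binding
  step, so basal (actin-free) ATPase activity is not emergent. It is
  treated as an additive offset in Michaelis-Menten fitting only
  (`fit_michaelis_menten(..., with_basal_offset = TRUE)`).
* **No calcium/calmodulin regulation, no temperature scaling.** Rate
  sets are per-temperature; the packaged presets are the 20 C sets.

Because the ligands are clamped the master equation is linear,
`dy/dt = Q y`, with `Q` assembled by `build_generator()`. Two solvers
are provided: `lsoda` with absolute tolerance 1e-10 and relative
tolerance 1e-8 (the rates span 0.01-4000 1/s, about five orders of
magnitude, so a stiff-capable integrator is the default) and an exact
spectral propagator (`method = "eigen"`) that diagonalises `Q` once per
parameter set. The spectral route is used inside fitting loops, where
thousands of forward simulations are needed, and falls back to `lsoda`
when the eigenbasis is ill-conditioned. Both routes are cross-checked
against each other and against the null-space steady state in the test
suite (agreement to 1e-5).

`steady_state_occupancy()` solves the stationary distribution from the
null space of `Q` (SVD). Under conditions that fragment the scheme into
several closed classes (for example all ligands zero, which makes both
detached end states absorbing) the stationary state is not unique; the
function then demands a starting state and returns the long-time limit,
rather than silently picking a null vector. `steady_state_flux()`
reports the net flux through the phosphate-release step; at steady state
the net flux through every step of the single cycle is equal (asserted
to 1e-8 in the tests), which is the meaningful conservation check for a
driven cycle where detailed balance intentionally fails.

## Stopped-flow experiments

`simulate_stopped_flow()` encodes one initial condition per experiment:

* *ATP-induced dissociation* and *ADP inhibition* start from the
  nucleotide-free open/closed equilibrium set by `K_alpha` (with ADP
  pre-equilibrated across AM/AM'/AM'D in the inhibition experiment).
* *Actin binding* starts from detached myosin.
* *Actin chase* models displacement of labelled actin under excess
  unlabelled actin: no rebinding, and the nucleotide-free isomerization
  is frozen so the observed rate is the actin off-rate itself (the
  closed state is treated as silent on the chase timescale).
* *Phosphate release* starts from the detached post-hydrolysis state
  (the ATP pre-mix is assumed complete, consistent with the scheme
  having no M + ATP step) and reports cumulative released phosphate,
  mimicking a phosphate-sensor signal.
* *Tryptophan hydrolysis* reports the approach of detached M'T to the
  hydrolysis products at the lumped rate.

**Pyrene convention.** Pyrene-actin fluorescence is quenched in strongly
bound states. The default bright set is all detached species *plus*
AM'T: the weak-binding isomerization AMT -> AM'T already unquenches the
dye. This is the convention under which the fast-phase plateau of
ATP-induced dissociation equals the isomerization rate `k_+2` (37 1/s)
rather than the slower subsequent actin release (10.1 1/s). The bright
set is an argument (`signal_convention`) and can be replaced by any set
of species.

**Exponential fitting.** `fit_exponentials()` uses separable least
squares: for fixed rates the amplitudes and offset are linear and are
profiled out by QR; only the log rates are optimised, from multiple
seeded starts spread log-uniformly over the resolvable window
`[0.1/t_max, 10/dt_min]`. This makes the fit deterministic, robust to
poor starting values, and exact on noiseless data. Phases are reported
fast-first.

## What the idealized identities do and do not guarantee

Two classical identities are used to read elementary constants off
secondary plots, and both are *limit* statements:

* `A_fast/A_slow = K_alpha` at saturating ATP requires the fast phase
  to be much faster than the pocket isomerization. At the packaged
  constants the separation is only about 9-fold (37 vs ~4 1/s), plus a
  ~7 1/s reverse isomerization of the ATP pocket for the 35-residue
  isoform. The exact solution of the scheme (confirmed by an
  independent three-state closed form) then gives amplitude ratios of
  ~0.6 (`myo1c0`) and ~1.5 (`myo1c35`) instead of 0.90 and 3.70. The
  test suite asserts the limit property: when the separation is scaled
  up the simulated ratio converges to `K_alpha` within 2%.
* The ADP-inhibition plateau `k_obs,slow -> k_+5` assumes displacement
  without ADP recapture. With ADP clamped, recapture
  (`k_-5 [ADP]` ~ 4/uM/s) competes with the *saturated* effective ATP
  capture rate (~33 1/s), so above roughly 5 uM ADP the simulated slow
  rate keeps decreasing instead of plateauing. Analyses therefore
  titrate ADP over 0.05-2.5 uM (at least 10x the apparent affinity,
  where recapture is negligible).

These are properties of the published constants, not numerical
artefacts; they are documented here because a user comparing raw
simulated amplitudes against tabulated equilibrium constants will
otherwise suspect the integrator.

## Steady state and duty ratio

`simulate_atpase_curve()` evaluates the stationary flux over an actin
grid; `fit_michaelis_menten()` extracts `k_cat`, `K_app.actin` and the
initial slope `k_cat/K_app`. Note the scheme is not exactly hyperbolic:
at very high actin, rebinding of the detached ATP state suppresses the
(detached) hydrolysis step, so fitted constants depend mildly on the
grid; the packaged tests use 1-300 uM, matching the published fitting
range.

Two duty-ratio estimates are provided. The two-rate formula
`k_+4/(k_+4 + k_+5)` uses phosphate release as the gate into the
strongly bound states and ADP release as the gate out.
`duty_ratio_occupancy()` instead sums the stationary occupancy of the
strongly bound species (AM'D, AM, AM'). The two agree when product
release dominates the cycle time (a tested limit), but they are not
interchangeable at the packaged constants: applying the formula to the
truncated-construct rates gives 0.057/0.103, while the occupancy route
gives ~0.056 for the short isoform. Published duty ratios for these
constructs (0.044/0.075) are consistent with neither route applied
verbatim to the tabulated rates (they imply an effective k_+4 of about
0.07 1/s); the package reports both estimates and leaves the
reconciliation to the user rather than hiding the discrepancy.

## Constrained global fitting

`run_global_fit()` reproduces the global-fit procedure used with
numerical-integration fitting software: the experimentally determined
parameters (ATP affinity and isomerization of the dissociation
experiment, lumped hydrolysis, ADP release, pocket equilibrium, and the
steady-state initial slope, which enters through the ATPase data set)
are held as hard equality constraints, and the remaining constants are
optimised on log scale by weighted Levenberg-Marquardt
(`minpack.lm::nls.lm`) against all data sets simultaneously. Weights
are 1/sd per point (so the objective is the usual chi-square with
1/sd^2 weighting). Multi-start (default 8 starts, log-uniform
perturbation within a factor of 5, first start unperturbed) guards
against local minima; the best start wins and the per-start objectives
are reported. Bounds default to a factor of 100 around the template. A
soft-constraint mode replaces fixed values with narrow log-normal
priors for sensitivity analysis.

Not every rate constant is identifiable from such data. Reverse rates
of rapidly pre-equilibrating binding steps enter only through their
equilibrium constant: the actin re-attachment step of the
post-hydrolysis head, for example, is determined as `K_9` but not as
`k_+9` and `k_-9` separately. The recovery exercises in the tests
therefore free an identifiable set (`k_+4`, `k_+9` with `k_-9`
constrained, `k_+A`, `k_-5`, `k_-2`) and `profile_parameter()` provides
a chi-square profile diagnostic that flags flat directions instead of
failing.

## Mechanics

The frictional-loading model gives the resistive force per filament
from surface-attached alpha-actinin crosslinkers,

F = (kappa/k_D) v zeta L r (k_A chi [a]^{5/2}) / (k_A chi [a]^{3/2} + k_D),

with the published limits (5/2-power growth at low concentration,
linear at high). The typeset grouping of this relation is ambiguous in
print; the implemented reading is the one consistent with the printed
symbols and limits, and it is isolated in `friction_force()` so an
alternative grouping is a one-line change. Only the linkage stiffness
range (0.2-0.5 pN/nm; default 0.35) and the interaction reach
(r = 61 nm) are experimentally anchored. The surface constants
`zeta`, `chi`, the crosslinker rates and the filament length are not
published; the defaults (`friction_params()`) were chosen once to place
the ensemble stall near 600 pN, i.e. ~5 pN per motor for the ~120
motors estimated to interact per filament, which puts the velocity-decay
midpoint near 22 nM crosslinker for the short isoform. Absolute force
calibration is therefore user-supplied; only shape and limit properties
are asserted quantitatively.

Velocity under load follows the sequential two-step detachment model: a
force-independent transition `k_i` and a Bell-type force-dependent
transition `k_f(F) = k_f0 exp(-F d / kBT)`, giving
`v(F) = w / (1/k_i + e^{F d/kBT}/k_f0)` with the working stroke `w`
fixed in fits (it cannot be separated from the absolute rate scale in
ensemble gliding data). `kBT` defaults to 4.28 pN nm (37 C, the
motility-assay temperature). The distance parameter `d` is not
published for these constructs; the default of 5 nm is the order of
magnitude established for the murine homolog by single-molecule work,
it is always explicit in parameter objects and reports, and with it the
short isoform's force-power curve peaks at ~0.058 aW near 1.8 pN,
consistent with the published ~0.05 aW at ~2 pN. Peak power and its
force are located by golden-section refinement of a dense-grid argmax
(`power_curve()`), with the per-motor convention P = F v / n_motors.
Absolute peak values for the 35-residue isoform depend on the unknown
`d`; what the model robustly reproduces is the order-of-magnitude
power contrast between the isoforms (a factor of ~13-15 with a common
`d` and the observed 4-fold difference in required motor density,
against a measured 18-fold change).

## Synthetic data

The generators (`gen_transient_series()`, `gen_atpase_table()`,
`gen_frictional_loading()`) are pure functions of their arguments and a
mandatory seed, and their zero-noise output is exactly the forward
model. Default noise matches the order of the published error bars:
absolute Gaussian noise of 1% of the signal span on fluorescence,
0.005 1/s on ATPase rates, 5% relative on velocities. The
frictional-loading generator solves the operating point
self-consistently (the frictional force is proportional to velocity, so
the gliding velocity is the fixed point of the force and force-velocity
relations).

What the generators do *not* emulate: instrument dead time,
photobleaching, lamp drift, inner-filter effects, arbitrary fluorescence
scaling between traces, and ligand depletion. Passing recovery tests on
these data therefore validates the analysis chain and the
identifiability of the parameters, not robustness to instrument
systematics.

## Problem sizes and numerical choices

The packaged tests and the acceptance analyses run at deliberately
modest sizes, which are entirely adequate for the stiff 9-state system:
transients with 120-800 grid points, ATPase curves with 8-15 actin
concentrations, recovery exercises with 5 noise seeds and 2-3 optimizer
starts, and 200-point force grids refined by golden section.
Tolerances: ODE atol 1e-10 / rtol 1e-8; steady-state residual 1e-10;
conservation asserted at 1e-6 along trajectories. Ties in exponential
fitting are avoided by reporting phases fast-first; degenerate inputs
(constant signals, two-point designs, zero slopes) error or flag rather
than returning silent numbers.

## Known limitations

* Chemistry and mechanics are linked only through shared rate constants
  (`k_i ~ k_+5` at 37 C), not through a combined mechanochemical state
  model; load-dependent kinetics inside the ATPase cycle are out of
  scope.
* The clamp approximation excludes substrate-depletion experiments.
* The amplitude-ratio and ADP-plateau identities are idealizations (see
  above); simulated secondary analyses reproduce the published *rates*
  well but the amplitude-derived equilibria only in the
  large-separation limit.
* Absolute frictional forces require user-supplied surface calibration.
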