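---
title: "Modeling diameter-dependent dendritic calcium dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling diameter-dependent dendritic calcium dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroca)
```

## The problem

Peak dendritic calcium levels are largely set by the surface-to-volume ratio
(SVR) of each branch: influx scales with membrane area while the concentration
change scales with the volume that dilutes it. Since the SVR of a cylinder is
inversely proportional to its diameter, any local diameter variation produces
spatial calcium gradients. Whether a compartmental model reproduces those
gradients depends on implementation details that are easy to get wrong:

* **Single-pool models** often use a submembrane shell volume of
  `surface x depth`, which has a *constant* SVR of `1/d` -- such a model
  predicts identical transients in every branch regardless of diameter.
* **Radial 1D diffusion models** discretize the cross-section into concentric
  shells whose depths are tied to the compartment diameter; the realized
  submembrane shell depth then drifts with diameter and perturbs the
  conversion of membrane current into concentration.

`dendroca` implements both model families under their correct and legacy
conventions, quantifies the disagreement, and provides an axisymmetric
(r,z) continuum solver and morphology statistics to study how much detail a
faithful model needs.

## Single-pool models

The pool obeys

$$\frac{d[\mathrm{Ca}]_i}{dt} = -\frac{I_{Ca}(t)}{2 F d_{eq}}
  - \beta\,([\mathrm{Ca}]_i - [\mathrm{Ca}]_0)$$

with resting level 45 nM. Two conventions resolve the equivalent depth
$d_{eq}$ from the nominal shell depth $d$:

* `SP_old` (legacy): $d_{eq} = d$. The shell volume is $\pi\,diam\,L\,d$,
  SVR $= 1/d$, diameter-independent.
* `SP_new` (corrected): $d_{eq} = d - d^2/diam$, the depth that multiplied by
  the surface area gives the true annular volume $\pi d\,(diam-d)\,L$;
  SVR $= diam/(d(diam-d))$.

Because the equation is linear, both conventions driven by the same influx
have above-rest responses in the exact ratio $d/d_{eq}$ at every time point;
the package integrates the pool with an exact exponential update per step, so
this identity holds to round-off and is asserted at `1e-9` in the tests.
Default parameters $d = 0.169\ \mu m$ and $\beta = 6.86\ \mathrm{ms}^{-1}$ are
the values fitted for Purkinje-cell dendritic calcium spikes.

**Geometric validity.** The corrected convention needs $d_{eq} > 0$, i.e.
$d < diam$. We deliberately accept depths between $diam/2$ and $diam$: beyond
$diam/2$ the picture of an annulus with a positive core radius degenerates,
but the volume formula $\pi d(diam-d)L$ stays positive and below the full
compartment volume, and it is exactly what the corrected pool mechanism
evaluates -- the fitted default depth of 0.169 um applied to sub-0.35-um
dendrites lives in this regime, so rejecting it would make the standard
parameterization unusable on thin branches. Only $d \ge diam$ is rejected as
an invalid geometry; error-grid audits flag and skip such cells.

## Radial shell discretization

Three schemes build a `shell_stack` (depths ordered from the membrane
inward; annular volumes; interface areas at the shared radii):

* **Variable depth (DM)** -- the classic scheme: `Shells = floor(diam/(4d) + 1.5)`
  shells; outermost and innermost have depth `d1 = diam/(4(Shells-1))`,
  intermediates `2 d1`. The realized `d1` drifts between `0.75 d` and
  `1.25 d` (for at least 3 shells), e.g. exactly 0.075 um at `diam = 0.6`,
  `d = 0.1` um.
* **Fixed depth (DM_FD)** -- `ceiling(diam/(2d))` shells of depth `d` with an
  adjusted core; the submembrane depth never varies. This is used as the
  reference scheme in all audits.
* **Hybrid** -- a fixed outer depth with the remaining radius split equally
  over a prescribed number of inner shells; used to separate the
  submembrane-conversion error from the interior-discretization error when a
  diameter-independent shell count is imposed.

Depth and volume closure (sums equal radius and full volume) hold to `1e-12`
relative by construction and are tested on a diameter grid. Floor/ceiling
formulas are evaluated with a `1e-9` tolerance so diameters carrying float
round-off (e.g. accumulated by `seq()`) land on the literal integer-boundary
values of the printed formulas. Diameters too thin for two variable-depth
shells (below 0.2 um at `d = 0.1`) are rejected by the constructor; sweep
audits substitute the single full-radius shell there, where the two schemes
coincide exactly.

## Buffered reaction-diffusion

The detailed model evolves free calcium plus buffers over the shells of one
or more compartments:

* **Calbindin**: 0.16 mM, four sites as two independent classes (two
  high-affinity/slow: $k_{on} = 5.5\ \mathrm{mM^{-1}ms^{-1}}$,
  $k_{off} = 0.0026\ \mathrm{ms^{-1}}$; two medium/fast: 43.5 / 0.0358),
  80% mobile with $D = 0.028\ \mu m^2/ms$.
* **Parvalbumin**: 0.08 mM, two sites, fully mobile
  ($D = 0.043\ \mu m^2/ms$), calcium kinetics 107 / 0.00095 with competing
  magnesium binding (0.8 / 0.025 at 0.59 mM free Mg, held constant).
* **Free calcium**: $D = 0.223\ \mu m^2/ms$.
* **Surface pump**: density $10^{-15}\ \mathrm{mol\,cm^{-2}}$,
  `pump + Ca <-> pumpCa -> pump` with $k_f = 3000\ \mathrm{mM^{-1}ms^{-1}}$,
  $k_b = 17.5$, $k_{ext} = 72.55\ \mathrm{ms^{-1}}$, attached to the
  submembrane shell with its density converted to a concentration through the
  shell's area and volume.

These kinetic constants are not free parameters of this package: they are the
published values of the standard Purkinje-cell calcium-dynamics model
literature, shipped as a clearly labeled default configuration
(`default_buffers()`, `pump_spec()`); every comparison that depends on them
is tolerance-based. Mobile and immobile calbindin fractions are tracked as
separate sub-pools with identical kinetics; free and bound buffer diffuse
with the buffer's coefficient, as in shell-based simulator practice.

**Resting balance.** The pump extrudes calcium at rest, so with
`leak_balance = TRUE` (default) a constant compensating leak is sized such
that the full network is exactly stationary at 45 nM. This makes "constant at
rest" a testable property rather than a slow drift.

**Conservation audit.** Every simulation tallies cumulative influx, leak and
extrusion as amounts; the audit series (free + buffer-bound + pump-bound +
extruded - influx - leak) is constant to better than `1e-8` relative in the
tests (typically `1e-12`).

## Influx

Calcium enters through a P-type permeability obeying the GHK current
equation ($P_{max} = 5.2\times10^{-5}$ cm/s in single-compartment work, 2 mM
external calcium, 34 C). The removable singularity at $V = 0$ is evaluated by
its analytic limit, keeping the current continuous in voltage.

The depolarizing command is a ramp-like step: hold -60 mV for 10 ms, ramp
linearly to -20 mV over 10 ms, hold the plateau for 100 ms, then step back to
-60 mV for a 60 ms decay tail. The return leg is our addition so traces are
genuine transients -- peak-centered integration windows and decay-time
comparisons are meaningless for a command that never repolarizes. The gate
defaults to a Boltzmann steady-state activation (half-activation -19 mV,
slope 5.5 mV, typical of high-threshold P-type channels) rather than an
always-open pore: with a voltage-independent open channel, the GHK driving
force is *largest* at the hyperpolarized holding level, so the "transient"
would be inverted and there would be no resting baseline. All error and ratio
quantities compare mechanisms under identical influx, so neither choice moves
a comparative result. Prescribed current-density waveforms (including
alpha-pulse spike bursts) are supported in place of the GHK drive, and
`ghk_waveform()` freezes a GHK drive into a prescribed waveform with calcium
clamped at rest when byte-identical influx across mechanisms is wanted.

## Numerics

* **Pool**: exact exponential integrator, default `dt = 0.02` ms,
  unconditionally stable; with prescribed influx the recursion is evaluated
  vectorized.
* **Radial / axisymmetric reaction-diffusion**: Strang splitting per step --
  half-step local reactions (classical RK4 with sub-steps; the stiffest local
  rate, pump extrusion at ~90/ms, sits well inside the RK4 stability region
  at the default sub-step of 0.005 ms), a full Crank-Nicolson tridiagonal
  diffusion solve per mobile species, then the second reaction half-step.
  Cross-compartment (longitudinal/axial) exchange is explicit; those
  couplings act over multi-micron distances and are far from any stability
  limit. The flux-form diffusion conserves matter to round-off.
* **Time step for scheme audits.** The DM-vs-DM_FD audit reports the
  *spatial-discretization* difference between two shell layouts. The
  fully-coupled implicit solvers of the standard simulators do not carry
  splitting error, so we run this audit at `dt = 0.005` ms, where the
  measured difference is converged (halving `dt` again changes the headline
  number in its third digit); at `dt = 0.02` the splitting error of *our*
  integrator would contaminate the thin-compartment cells where 0.05-um
  shells make interface transfer fast. Routine simulations use the
  conventional 0.02 ms.
* **Longitudinal coupling across unequal shell counts** apportions exchange
  over the overlap of the two radial partitions (annular area over the
  distance between compartment midpoints), which is strictly conservative
  and removes the common simulator restriction that neighbors must share a
  shell count. The same construction couples axial slabs of different radii
  in the (r,z) solver.
* **Degenerate inputs**: non-positive geometry raises a typed
  invalid-geometry error naming the offending values; zero-length traced
  intervals are collapsed during compartmentalization and counted; pairs
  with non-positive values are skipped (and counted) in ratio histograms.

## The axisymmetric reference solver

A deterministic (r,z) finite-volume discretization of the same reaction
network on cylinders or stacked frusta replaces particle-based 3D simulation:
at the influx densities of interest the molecule counts are large enough that
stochastic fluctuations average out, so a continuum reference is both
faithful and fast. Closed ends are no-flux; lateral surfaces, exposed annular
steps between slabs of different radii, and (optionally) the end caps carry
membrane influx, pump and leak. On a uniform cylinder with lateral-only
influx the solution is z-invariant and its submembrane trace matches the 1D
radial model within 2% (test-asserted); with caps as membrane, terminal slabs
accumulate visibly more submembrane calcium than the mid-shaft -- the
closed-end tip effect.

## Morphology analysis and synthetic fixtures

`read_swc()` parses standard 7-column SWC with structural validation (single
root, acyclicity, positive radii; errors carry line numbers). Unbranched
segments are maximal paths between junctions, with the upstream junction
point shared into each child segment. Per-segment diameter CV uses the
sample (n-1) standard deviation; soma-typed points are excluded.
`compartmentalize()` converts segments to cylinders either one-per-segment
(length-weighted mean diameter) or one per traced interval (two-point mean
diameter); both preserve total path length to `1e-9`.

The tree generator (`generate_tree()`) emulates the aspects of real
reconstructions that the analyses consume: branching topology, within-segment
taper, diameter steps at branch points, and controlled within-segment
diameter variability (multiplicative Gaussian noise truncated at three sigma,
floored at 0.05 um, so the realized CV tracks the target -- recovery within
0.05 is test-asserted at the 0.2 and 0.4 levels flagged as common in real
reconstructions). It does *not* emulate realistic arbor statistics (segment
length distributions, branch angles, soma geometry) or reconstruction
artifacts such as z-axis shrinkage and quantized diameters, so passing tests
demonstrate correctness of the mechanisms and metrics, not that any
particular real neuron's calcium map is reproduced.

## What the shipped analyses show

Running the package's own audits (also exercised by `scripts/acceptance.R`
and the test suite):

* The legacy pool volume underestimates peak calcium everywhere, with errors
  growing as diameters shrink (about 50% at 0.1 um diameter for the
  geometrically valid depth grid) -- and it predicts *no* diameter dependence
  at all.
* The variable-depth and fixed-depth diffusion schemes agree to within a few
  percent in peak submembrane calcium across 0.1-6 um and a four-fold influx
  range (largest magnitude about 4%), far below the up-to-±33% volume
  conversion difference of their submembrane shells: buffering and diffusion
  filter the geometric error strongly.
* Imposing a diameter-independent shell count is much worse: with 4 shells
  the peak errors exceed 10% beyond 2 um diameter; fixing only the
  submembrane depth leaves a smaller, one-signed error.
* Integrated-calcium ratio maps show that the corrected pool confines
  large (>2x) adjacent-compartment contrasts to sub-0.3-um members, while
  the buffered diffusion models extend that region to compartments of 1 um
  -- detailed dynamics are more sensitive to diameter variation than pools.

## Known limitations

* No endoplasmic reticulum, mitochondria, calcium-induced calcium release, or
  inhomogeneous channel densities; buffer concentrations are uniform.
* The voltage command is prescribed; there is no cable equation or
  calcium-activated channel feedback, so spike shapes cannot emerge from the
  model -- spike-driven influx is emulated by prescribed current waveforms.
* Longitudinal/axial exchange is explicit; for sub-micron compartment lengths
  combined with large time steps an implicit treatment would be preferable.
* The parvalbumin magnesium pool assumes constant free magnesium.
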