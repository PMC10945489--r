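---
title: "Liquid-vapor phase behaviour of rigid three-point water models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liquid-vapor phase behaviour of rigid three-point water models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(aquacoex)
library(dplyr)
```

## The problem

Rigid three-point water models (SPC, TIP3P and their descendants) are
parameterised around ambient conditions, yet they are routinely used at
elevated temperatures. How well do they reproduce the liquid-vapor part of
the phase diagram — the coexistence densities, the critical point
$(T_C, \rho_C)$, the enthalpy of evaporation $\Delta H$, the temperature of
maximum density $T_{MD}$, and the temperature at which a superheated liquid
spontaneously evaporates at constant pressure, $T_\mathrm{evap}$? And which
model parameters control that behaviour?

`aquacoex` implements the full analysis chain downstream of the molecular
dynamics engine. MD itself is out of scope: configurations, per-frame
observables and density traces enter as text files (GRO/XYZ, CSV), and a
seeded synthetic generator produces statistically faithful stand-ins for all
of them with known ground truth, so every stage is testable on a desktop.

## Electrostatic moments

Each model is three point charges: $-2q_H$ on the oxygen and $+q_H$ on each
hydrogen at bond length $d_{OH}$ and angle $\phi_{HOH}$. With the half-angle
$\theta = \phi_{HOH}/2$ the gas-phase dipole moment is
$$\mu = 2\,q_H\,d_{OH}\cos\theta,$$
and the tetrahedral quadrupole moment — the single scalar that summarises
the out-of-dipole charge arrangement of water, defined as
$\tfrac12(\Theta_{xx}-\Theta_{yy})$ of the traceless quadrupole tensor with
the molecule in the $xz$-plane, dipole along $z$ and origin at the oxygen —
reduces to
$$Q_T = \tfrac{3}{2}\,q_H\,d_{OH}^2\sin^2\theta.$$
We convert with $1\,e\cdot\text{Å} = 4.80320$ D (CODATA-derived); the unit
convention (D and D·Å) is asserted against widely tabulated literature
values for SPC/E ($\mu = 2.35$ D, $Q_T = 2.04$ D·Å), not against any single
source. `point_charge_moments()` recomputes both quantities by brute-force
summation over the explicit charge coordinates; the test suite requires
agreement with the closed forms to $10^{-10}$ relative. The extra repulsive
hydrogen site that distinguishes sTIP3P from TIP3P carries no charge and is
stored as a flag only.

```{r moments}
water_models() |> derived_moments()
```

## Slab profiles and interface fits

Coexistence simulations use an elongated box (20 × 20 × 100 Å holding
~512 molecules) with a liquid slab between two planar interfaces. The
analysis steps are:

1. **Centering.** The slab diffuses and eventually crosses the periodic
   boundary; a naive mean of $z$ is then meaningless. We map $z$ to the
   angle $2\pi z/L_z$, average the unit vectors, and translate the phase of
   the resultant to $L_z/2$. This is exact for any periodic translation,
   idempotent, and degrades gracefully: when the resultant length drops
   below 0.05 (an essentially uniform gas) the frame is returned unchanged
   rather than centered on noise. Correct centering is the step that
   becomes limiting near $T_C$, where the two phases blur.
2. **Histogramming.** Molecule reference sites (the oxygen atom; the
   difference from the centre of mass is far below one bin) are binned
   along $z$ with a default bin width of 0.5 Å (configurable; fine enough
   to resolve a ~3 Å interface, coarse enough for decent per-bin counts).
   Profiles conserve mass to $10^{-9}$ relative by construction.
3. **Interface fitting.** The double-tanh model
   $$\rho(z) = \rho_v + \frac{\rho_l-\rho_v}{2}\Big[\tanh\frac{z-z_{lo}}{w}
   - \tanh\frac{z-z_{hi}}{w}\Big]$$
   is fitted by Levenberg-Marquardt with a *single* width $w$ shared by
   both interfaces — per-interface widths add a parameter that near-critical
   profiles cannot constrain. Initial guesses come deterministically from
   profile quantiles. If the fitted gap $\rho_l-\rho_v$ falls below three
   times its standard error, the point is flagged `indistinct` and excluded
   from critical-point fitting by default: near $T_C$ a formally converged
   fit can be meaningless, and silently feeding it forward would bias
   $T_C$ downstream.

```{r slab, fig.alt = "Density profile with tanh fit"}
frames <- simulate_slab_frames(slab_spec(n_frames = 50, drift_per_frame = 0.8),
                               seed = 1)
fit <- fit_interfaces(density_profile(frames))
tidy(fit)
autoplot(fit)
```

## Critical point

Below $T_C$ the coexistence densities obey the universal scaling law and
the law of rectilinear diameters,
$$\rho_l - \rho_v = A\,(1 - T/T_C)^\beta, \qquad
\frac{\rho_l + \rho_v}{2} = \rho_C + B\,(T_C - T),$$
with the 3D Ising exponent $\beta = 0.326$ held fixed. We fit both laws
*jointly* with a shared $T_C$ (stacked, optionally $1/\sigma$-weighted
residuals under Levenberg-Marquardt) rather than sequentially: the joint
fit is statistically tighter and makes the two branches intersect at
$(T_C,\rho_C)$ exactly by construction. A free-$\beta$ mode exists but is
off by default — with typical temperature grids the exponent and $T_C$ are
strongly confounded, and the fixed-exponent convention keeps results
comparable across models. Initial guesses are deterministic
($T_C^0 = 1.05\,T_\max$; diameter line for $\rho_C^0, B^0$; lowest-$T$ gap
for $A^0$).

Points with a non-positive measured gap are rejected before fitting (merged
phases mean $T \ge T_C$), and a fit whose $T_C$ does not exceed every input
temperature is a domain error rather than a result.

Uncertainty comes from trajectory splitting: a 20 ns production run
analysed in four 5 ns splits gives per-block refits; the central value is
the pooled fit and the quoted spread is the standard deviation over blocks
(`block_estimates()`).

One analytic caveat documented here because it is easy to trip over: on the
fitted curves the *liquid* branch decreases monotonically up to $T_C$, but
the *vapor* branch only increases where the scaling term dominates,
i.e. for $1 - T/T_C < (2BT_C/A\beta)^{1/(\beta-1)}$. For amplitude/slope
combinations typical of water models the fitted vapor curve has a shallow
maximum far below $T_C$; this is a property of the two-law parameterisation,
not a bug.

```{r critfit, fig.alt = "Coexistence envelope with fitted critical point"}
tbl <- simulate_coexistence_table(seq(400, 620, 20), T_C = 640, rho_C = 300,
                                  A = 750, B = 0.85, noise_frac = 0.01,
                                  seed = 1)
cp <- fit_critical_point(tbl)
glance(cp)
autoplot(cp)
```

## Evaporation thermodynamics

From canonical simulations of pure liquid and pure vapor at matched
temperatures we take mean internal energies per molecule ($U_l$, $U_v$, in
kJ/mol; a kcal converter is provided) and densities. Then
$$\Delta U = U_v - U_l, \qquad
p\Delta V = p_\mathrm{sat}\,(v_v - v_l), \qquad
\Delta H = \Delta U + p\Delta V,$$
with molar volumes $v = M/\rho$ and $1\,\text{L·bar} = 0.1$ kJ. The
saturation pressure is the mean pressure reported by the vapor simulation
when available; otherwise the ideal-gas estimate
$p = (\rho_v/M)RT$ — accurate to a few percent at coexistence vapor
densities below ~550 K. The liquid molar volume is kept in $p\Delta V$
(not approximated away), so the identity
$\Delta H = \Delta U + p\Delta V$ holds to machine precision for every
input; the test suite asserts it at $10^{-12}$. In the liquid regime
(liquid ~900-1000 g/L, vapor below ~50 g/L) the volume work is an order of
magnitude smaller than $\Delta H$, which the suite checks as a sanity
property of the pipeline.

## NPT analysis: density maximum and spontaneous evaporation

**Density maximum.** Mean NPT densities at low temperatures are
interpolated with a weighted quartic polynomial in $T$ (centered for
conditioning), and $T_{MD}$ is the analytic stationary point with negative
curvature inside the sampled range. The quartic is our stand-in for the
empirical liquid-density interpolation functions used in this field; it
nests a parabola exactly and the fit family sits behind the single
`fit_density_maximum()` interface so it can be swapped. Uncertainties on
$T_{MD}$ and $\rho_{MD}$ are delta-method propagations of the coefficient
covariance; block-splitting (6 × 5 ns, first block discarded,
`split_uncertainty()`) provides the per-temperature input spreads.

**Spontaneous evaporation.** Above a model-dependent temperature the
metastable superheated liquid collapses to vapor — the box expands
explosively. This is *not* the boiling point: no bubbles nucleate in these
small periodic systems, and the transition happens above $T_B$ in the
superheated regime. Since no sharp numeric criterion exists in the
underlying physics, the detector uses an explicit, configurable rule: a
step counts as evaporated when the mean density over the final 20% of its
trace is below $0.5\,\rho_\mathrm{liquid}^\mathrm{ref}$; the onset is the
first crossing below that threshold that never recovers above
$0.8\,\rho_\mathrm{liquid}^\mathrm{ref}$ (hysteresis against transient
dips). Raising the threshold can only flip a verdict from liquid to
evaporated, never back — a monotonicity the tests assert on a threshold
grid. `estimate_T_evap()` walks a heating ladder (default 1 K steps, 5 ns
per step — a 0.2 K/ns average heating rate, slow enough for converged
transition temperatures at these system sizes) and reports the lowest
evaporated step, warning if a hotter step stayed liquid.

Barostat choice and density pre-equilibration shift the apparent
$T_\mathrm{evap}$ (Berendsen ~20 K higher than stochastic cell rescaling,
Parrinello-Rahman ~10 K lower; skipping pre-equilibration ~5-10 K lower).
These are carried as metadata labels on traces and never applied as
automatic corrections: silently "fixing" data by a rule of thumb would be
worse than reporting what was measured.

## Cross-model correlations

`linear_fit()` is ordinary least squares with $r^2$ the squared Pearson
correlation; `offset_fit()` is the one-parameter model $y = x + c$,
$c = \overline{y-x}$, with $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$
about the mean of $y$ — nested in the linear fit, so its $R^2$ can never
exceed the linear one (a property test). `property_scan()` correlates every
registry parameter plus $\mu$ and $Q_T$ against a target column and ranks
by $r^2$; on the bundled tables $Q_T$ predicts $T_\mathrm{evap}$ markedly
better than $\mu$ does. Table uncertainties are carried but not used as fit
weights (plain fits are the convention for these cross-model comparisons;
weighted variants can be built from the same columns). The experimental row
is excluded from all cross-model fits and kept only for reference
differences such as $T_C^\mathrm{exp} - T_{MD}^\mathrm{exp} \approx 371$ K.

```{r correlations}
tbl2 <- phase_diagram_points(include_experiment = FALSE)
linear_fit(tbl2, T_C, rho_C)
offset_fit(tbl2, T_C, T_evap)
suppressWarnings(property_scan(tbl2, T_evap))
```

## What the synthetic generators do and do not emulate

The generators exist so that every analysis stage has inputs with known
ground truth:

- `simulate_slab_frames()` draws molecule positions independently from the
  double-tanh density (inverse-CDF in $z$, uniform in $x,y$) and applies a
  rigid per-frame drift to exercise periodic re-centering. Defaults
  (1000 vs 10 g/L, interfaces at 30/70 Å, width 3 Å, 200 frames in a
  20 × 20 × 100 Å box, ~540 molecules) mirror the coexistence geometry
  described above at a mid-range temperature. There is no excluded volume,
  no hydrogen-bond structure and no interfacial capillary-wave spectrum:
  passing tests demonstrate the correctness of centering, histogramming and
  fitting, not the realism of water structure.
- `simulate_coexistence_table()` inverts the two coexistence laws exactly
  and applies multiplicative Gaussian noise (default study condition: 1%,
  the order of the relative spreads obtained from trajectory splitting).
- `simulate_heating_ladder()` models each step as a discrete
  Ornstein-Uhlenbeck process around a linearly decreasing equilibrium
  density (960 g/L at 300 K, slope 0.9 g/L/K — liquid water's decade-scale
  slope at elevated temperature), with relaxation time 0.05 ns and
  stationary spread 15 g/L; above the true transition an exponential
  waiting time (mean 1 ns per 5 ns step) precedes a 0.3 ns linear collapse
  to 5 g/L. Collapse microphysics (nucleation kinetics, system-size
  effects) is deliberately not modelled — only the detector's contract
  needs exercising. With these conditions the ladder estimator's median
  error is dominated by the strict-inequality convention (steps strictly
  above the truth collapse), i.e. about one step.

All generators take an explicit seed, restore the caller's RNG state, and
attach their ground truth to the output for downstream comparison.

## Numerical choices and degenerate inputs

- Internal units everywhere: Å, K, bar, g/L, kJ/mol; conversions happen
  only at I/O boundaries (GRO is nm-based and multiplied by 10 on read).
- Histogram bins snap to tile $L_z$ exactly, so mass conservation is exact
  rather than approximate at the box edge.
- Both nonlinear fits use deterministic initial guesses (no random
  restarts) and bounded Levenberg-Marquardt; non-convergence is reported
  with diagnostics (interface fits return a flagged result, critical-point
  fits raise an error quoting the initial guesses).
- Degenerate contracts: uniform gas → centering is the identity; flat
  profile → `indistinct`; ladder that never collapses → "not reached"
  result, not an error; strictly monotone density samples → "no maximum in
  range" error; single block → error.

## Problem sizes

The shipped tests and the acceptance script run the study conditions at
desk scale: 200-frame slabs of ~540 molecules, 12-point temperature grids
over 400-620 K with 20 noise seeds, 10 ladders of 41 × 500 samples, and the
11-model bundled tables. The full suite completes in well under a minute.
Per-model phase diagrams at MD fidelity are upstream of this package by
design.

## Known limitations

- The rectilinear-diameter law is itself an approximation; non-linear
  diameter corrections would likely shift $T_C$ slightly and are not
  implemented. The strong linear correlation between fitted $T_C$ and
  $\rho_C$ across models is partly imposed by this fitting convention.
- Offset-only and linear correlations on the bundled characteristic-point
  table use the printed (rounded) values; statistics computed from them can
  differ in the second decimal from values computed on unrounded data.
- The evaporation criterion (0.5/0.8 hysteresis) is a documented
  convention, not derived physics; conclusions about $T_\mathrm{evap}$
  inherit its arbitrariness within roughly one ladder step.
- GRO/XYZ readers handle orthorhombic boxes only, matching the slab
  geometry; binary trajectory formats are out of scope.
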