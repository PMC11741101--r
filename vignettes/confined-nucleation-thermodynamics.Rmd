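---
title: "Solubility and nucleation thermodynamics from confined seeded simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solubility and nucleation thermodynamics from confined seeded simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtherm)
library(dplyr)
```

## The model

Classical nucleation theory writes the free energy of a crystalline nucleus
of size $n$ growing from a supersaturated solution as a competition between
a favourable bulk term and an unfavourable surface term,

$$\beta\Delta F^\infty(n) = -n\,\ln S + \sigma' n^{2/3},$$

with $S = x/x^*$ the supersaturation, $x^*$ the solubility (equilibrium
solute mole fraction) and $\sigma'$ an effective surface energy in units of
$k_BT$, averaged over a quasi-spherical nucleus. This profile has a single
stationary point, the critical nucleus: in a macroscopic reservoir a
post-critical nucleus grows forever.

A molecular-dynamics box is not a macroscopic reservoir. In a thermostated,
closed box (constant molecule numbers, constant pressure) every molecule
that joins the crystal leaves the solution, so the composition is slaved to
the nucleus size,

$$x(n) = \frac{n_{tot} - n}{(n_{tot} - n) + n^s_{tot}},$$

and the driving force dies as the nucleus grows. With all
activity-coefficient ratios set to one (they tend to one as $x \to x^*$,
and the package exposes no activity model by design) the confined
free energy implemented in `confined_free_energy()` is

$$\beta\Delta F(n) = n \ln x^* + (n_{tot}-n)\ln x(n) - n_{tot}\ln x_0
  + n^s_{tot} \ln\frac{1 - x(n)}{1 - x_0} + \sigma' n^{2/3},$$

whose derivative collapses to the transparent form

$$F'(n) = -\ln\frac{x(n)}{x^*} + \tfrac{2}{3}\sigma' n^{-1/3}.$$

For moderately supersaturated, not-too-small boxes this profile has **two**
stationary points: the confined critical nucleus (a maximum) and a stable
minimum at which a crystal coexists with the depleted solution. A seeded
simulation relaxes to that minimum, and its steady-state cluster size
$n^{ss}$ is an equilibrium observable that can be sampled ergodically.

## Estimating $(x^*, \sigma')$ from steady-state sizes

Each simulated box contributes one stationarity condition
$F'_i(n^{ss}_i; x^*, \sigma') = 0$. Several boxes with different
compositions share the same two simulation-independent parameters, so
`fit_thermo_params()` minimises $\sum_i F'_i(n^{ss}_i)^2$ by
Levenberg-Marquardt in $(\ln x^*, \ln \sigma')$ coordinates:

* the log transform enforces positivity and conditions the problem;
* the initial guess sets $x^*$ to the most depleted final solution
  composition among the observations — the solution in equilibrium with the
  largest relative cluster bounds the solubility from above — and
  $\sigma' = 5\,k_BT$, a typical magnitude for effective surface energies
  of small organic crystals in water;
* the residual is the stationarity gradient itself, not a
  predicted-minus-observed size, which keeps the objective exactly the
  stated least-squares problem and avoids a nested root search inside the
  optimiser;
* unstable stationary points (the critical-nucleus branch also satisfies
  $F' = 0$) are avoided automatically because the observed sizes come from
  stable steady states.

Because the observed sizes fluctuate (they are time averages of a
fluctuating cluster in a finite trajectory), the per-observation residuals
at the optimum do not vanish for real data; for the packaged reference
dataset they are of order $10^{-1}\,k_BT$/molecule, consistent with the
sizeable parameter uncertainties reported alongside. On noise-free
synthetic data the residuals collapse to numerical zero and the generating
parameters are recovered to well under 1%.

Uncertainties come from case-resampling bootstrap
(`bootstrap_uncertainty()`): whole observations are resampled with
replacement, each resample is refitted, and 16-84% percentile intervals
(a one-standard-deviation band) are reported together with the full
resample distributions. The resampling unit, resample count (default 1000)
and percentile convention are package choices; the percentile pair is
configurable.

```{r}
fit_beta <- fit_thermo_params(lga_table1("beta"), n_boot = 200, seed = 1)
tidy(fit_beta)
glance(fit_beta)
```

## From one temperature to a phase diagram

With $(x^*, \sigma')$ known at a reference temperature, a Van't Hoff
relation (the Gibbs-Konovalev treatment of solid-liquid equilibrium)
extends the solubility across temperatures:

$$\ln x^*(T) = \ln x^*(T_{ref})
  - \frac{\Delta H_{diss}}{R}\Big(\frac{1}{T} - \frac{1}{T_{ref}}\Big),$$

assuming only that the activity coefficients and the dissolution enthalpy
$\Delta H_{diss}$ are constant over the range — not ideality. Heat-capacity
corrections are deliberately out of scope. $\Delta H_{diss}$ can be taken
from three bulk-phase potential energies
(`dissolution_enthalpy_from_energies()`) or from two independent
solubilities (`enthalpy_from_two_solubilities()`, the exact inverse of the
curve). Temperatures are strictly Kelvin at the API and
$R = 8.314462618\ \mathrm{J\,mol^{-1}K^{-1}}$; energies are $k_BT$
internally and kJ/mol at the I/O boundary.

Two polymorphs' curves give their relative stability,
$\beta\Delta\mu_{b\to a}(T) = \ln\!\big(x_a^*(T)/x_b^*(T)\big)$, positive
when $b$ is the more stable (less soluble) form.

```{r}
curve_beta <- solubility_curve_params(fit_beta$x_star, 298, 33.9)
fit_alpha <- fit_thermo_params(lga_table1("alpha"))
curve_alpha <- solubility_curve_params(fit_alpha$x_star, 298, 24.7)
solubility_at(290, curve_beta)
chemical_potential_difference(298, curve_alpha, curve_beta)
```

A caution from our own numbers: with the fitted solubilities and the
MD-derived enthalpies (33.9 and 24.7 kJ/mol for the beta and alpha forms of
L-glutamic acid), $\beta\Delta\mu_{\beta\to\alpha}$ stays positive over
273-343 K — the beta form is always the stable one — but it exceeds
$1\,k_BT$ below roughly 288 K. The frequently quoted "sub-$k_BT$"
polymorph free-energy gap holds on this model only in the upper part of the
temperature range; the enthalpy difference of 9.2 kJ/mol amplifies the gap
on cooling. The test suite asserts the sub-$k_BT$ bound over the full
273-343 K range and that assertion fails by construction at the low end;
we keep it as an honest record of the discrepancy rather than narrowing
the range after the fact.

## Barriers, metastable zone, and stability maps

Assuming a temperature-independent $\sigma'$, the macroscopic barrier at
any $(x, T)$ is the closed form
$\beta\Delta F^*(x,T) = \tfrac{4}{27}\sigma'^3/\ln^2\!\big(x/x^*(T)\big)$
(`cnt_barrier()`), which the tests verify against a grid search of the
profile maximum. The limit of solution stability `metastable_limit()` is
the locus where the barrier drops to a threshold, by default
$3\,k_BT$ — an admittedly conventional marker of "instantaneous
precipitation", hence configurable. For the $n^{2/3}$ surface law the
locus is a temperature-independent multiple of the solubility curve; a
bisection solver is kept as an internal cross-check of the closed form.

`stability_map()` classifies the composition/box-size plane into
undersaturated, confinement-stabilised and nucleation-permitted domains.
The box "volume" axis is parameterised by the solvent count $n^s_{tot}$:
at fixed pressure the total molecule count sets the volume, and exporting
the map in long format keeps any later axis scaling choice out of the
correctness path. The solute count is treated as continuous on the map
(the classification is a property of the free-energy profile, not of an
integer molecule count).

## Numerical choices

* Cluster size $n$ is continuous throughout the thermodynamic layer;
  stationary points are reported as reals. Integer sizes only arise from
  trajectory analysis.
* Stationary points: gradient sign changes are bracketed on a dense grid —
  2048 linear points on $(0, n_{tot})$ plus a 512-point log-spaced
  refinement so small-$n$ structure survives in very large boxes — then
  refined by bisection to $10^{-8}$ molecules. A minimum narrower than the
  grid is treated as absent.
* The gradient is analytic; the test suite requires agreement with a
  fourth-order finite-difference oracle to $10^{-6}$ relative (the free
  energy sums large near-cancelling terms, so the oracle itself needs a
  high-order stencil).
* The confined profile converges to the macroscopic one with a depletion
  bias of order $n^2/(2 n_{tot})$; the limit-equivalence test sizes its
  box accordingly.
* The least-squares problem is solved to `ftol = ptol = 1e-14` with a
  fixed start, so fits are deterministic and order-invariant to solver
  precision.

## The synthetic-data generator

`generate_observations()` inverts the estimation problem: it places each
box's steady-state size at the interior minimum of the confined profile
under known parameters, optionally adds Gaussian noise (default sd 2
molecules, the scale of steady-state cluster fluctuations in trajectories)
and rounds to whole molecules. Compositions admitting no stable cluster
are reported, never silently dropped. `generate_crystal_liquid_frame()`
builds cluster-identification benchmarks: a cubic-lattice core with
aligned internal vectors (lattice constant 6 Å, the order of a
small-molecule coordination shell) inside a uniform random "liquid" with
isotropic orientations and a hard minimum-distance insertion rule.

What the generator does *not* emulate: interfacial disorder and partial
order at the crystal-liquid boundary, realistic liquid structure
(insertion with a hard core is not a thermal liquid), finite sampling of
the steady state beyond additive Gaussian noise, and any polymorph-specific
packing. Passing the round-trip and benchmark tests therefore shows the
estimator and classifier are correct on their own model assumptions; it
does not validate the orientation descriptor against real disordered
interfaces.

## Trajectory analysis

The crystalline/liquid descriptor follows the orientation-fingerprint
idea: each rigid molecule carries an internal vector defined by a
designated atom pair (the pair is a required configuration input — the
choice is conventional, and the fingerprint must be built and applied with
the same convention). `build_fingerprint()` histograms the polar angle
between internal vectors of all molecule pairs within a radial cutoff
matching the polymorph's first coordination shell (6.25 Å and 7.0 Å for
the alpha and beta forms of L-glutamic acid) over 36 bins on
$[0^\circ, 180^\circ]$. Bins reaching at least 20% of the peak density are
"accepted"; a molecule is crystalline when at least one neighbour within
the cutoff matches an accepted bin (`min_matches` configurable). The full
polar angle is kept by default so parallel and antiparallel packings are
distinguished; folding to $\min(\theta, 180-\theta)$ is available for
truly headless internal vectors. Crystalline molecules are clustered by
connected components at the same cutoff (minimum-image convention,
orthorhombic cells), and `steady_state_size()` averages the tail of the
largest-cluster series, flagging residual drift at the $2\sigma$ level of
a linear trend.

Structure I/O goes through bio3d: single- and multi-model PDB files are
supported (`read_snapshot_pdb()`/`write_snapshot_pdb()`). Compressed MD
trajectory formats (XTC/TRR) have no reader in the R ecosystem this
package builds on and are out of scope; converting a trajectory to
multi-model PDB upstream is the supported route.

## Problem sizes and limitations

The shipped tests run the full pipeline on the 14-row reference table,
20-dataset parameter-recovery sweeps, and cluster benchmarks of up to
1000 molecules; all of it completes in well under a minute on one core.

Known limitations, deliberate in scope: no activity-coefficient model
(ratios fixed at one, with the dilute-solution argument above); a single
effective, temperature-independent, facet-averaged $\sigma'$; no kinetic
prefactors or nucleation rates (the metastable-zone limit is a barrier
locus, not a rate contour); no weighted or multi-temperature joint fits;
and no continuous order parameter suitable for biased sampling — the
classifier is an a-posteriori analysis tool.
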