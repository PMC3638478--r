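---
title: "Residue functions of simulated cerebral capillary networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue functions of simulated cerebral capillary networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Perfusion imaging (dynamic susceptibility contrast MRI, arterial spin
labelling) characterizes a tissue voxel by its *residue function*
R(t): the fraction of an instantaneously injected intravascular tracer
still inside the vasculature a time t after arrival. R(0) = 1, R is
non-increasing, its integral is the mean transit time (MTT), and its
negative derivative h(t) = -dR/dt is the distribution of vascular
transit times, whose standard deviation is the capillary transit-time
heterogeneity (CTTH). Clinically R(t) is estimated by deconvolution;
`capres` goes the other way: it computes the *exact* residue function
of an explicit microvascular network model, so that changes in the
network (e.g. capillary occlusion in ischaemia) can be related to
changes in the parameters a clinician could estimate.

## Single vessel

Inside one vessel, tracer transport is taken as pure convection by a
Poiseuille plug at the mean velocity U: the concentration obeys
dC/dt + U dC/dx = 0. Axial diffusion is neglected (the capillary
Peclet number is of order 10) and so is any exchange with tissue. A
vessel of length L then delays its inlet concentration by the transit
time T = L/U = V/Q, and its volume-averaged impulse response gives a
*rectangular* residue function: R(t) = 1 on [0, T), 0 afterwards, and
h(t) a unit point mass at T (`single_vessel_residue()`).

## Networks: a sum of rectangles

For a network, steady flow fixes a direction on every perfused vessel,
and because pressure decreases strictly along flow, the perfused
(live) vessel graph is a directed acyclic graph. With a single
arterial impulse shared among the arteriole-capillary junction nodes
in proportion to their inflow, the tracer state at any node is a
finite *arrival spectrum*: atoms (w, tau) giving the probability w of
reaching that node along some pathway with accumulated delay tau. At
a junction, concentrations mix in proportion to flow, so an atom
propagates along a vessel (i to j) with its weight multiplied by the
flow fraction Q_ij / outflow(i) and its delay increased by T_ij.

Each vessel then contributes, per upstream atom, one rectangle to
R(t): height w * Q_ij / outflow(i), support [tau, tau + T_ij). The
whole residue function is the exact superposition of these rectangles,
assembled by a sorted breakpoint sweep (`network_residue()`); nothing
is ever put on a time grid. The normalization R(0) = 1 is *asserted*,
not imposed: it emerges from mass conservation at the flow solution,
so a deviation beyond 1e-6 signals a bookkeeping defect and raises an
error. The computation is a single dynamic-programming sweep in
topological order (`arrival_spectra()`); pathways are never
enumerated, although an explicit enumerator
(`enumerate_paths_residue()`) and a stochastic particle tracker
(`monte_carlo_residue()`) are provided as independent oracles and used
throughout the test suite.

Two numerical housekeeping rules bound the atom count: atoms whose
delays agree to 1e-9 (relative) are merged, and atoms with weight
below 1e-14 are dropped, with the dropped mass tracked and required to
stay below 1e-9 in total. (The per-atom prune threshold is well below
any meaningful probability; on path-rich networks of ~120 vessels the
sweep carries on the order of 1e5 rectangles in well under a second.)
Tracer that reaches a node with no live outgoing vessel — possible
only at the dead-flow tolerance floor — is counted into the same
dropped-mass budget.

Because every interior hand-off is mass-neutral (a rectangle ending at
a node is exactly replaced by the rectangles it spawns), R(t) drops
only at tracer arrivals at the venule outlets; h(t) therefore
coincides with the outlet arrival spectrum, which the tests exploit as
a consistency check.

## Network generation

Real human cortical capillary morphometry is published as summary
statistics, and the generator targets exactly those: in a 250 um
tissue cube, vessel density 7718 per mm^3, mean node degree
(connectivity) 3.22, vessel length 59.71 +/- 51.61 um, diameter
6.24 +/- 1.30 um, with 3 arteriole-capillary junctions on one cube
face and 2 capillary-venule junctions on the opposite face. The edge
count is `round(density * volume)` (121 at defaults — consistent with
the quoted "approximately 125 vessels") and the node count
`round(2 * edges / connectivity)` (75), so density and connectivity
are matched by construction. Node positions are uniform in the cube; a
Prim minimum spanning tree over Euclidean distances guarantees
connectedness, and the remaining edges are drawn from
k-nearest-neighbour pairs (short candidate vessels). Vessel *lengths*
are gamma-distributed and *diameters* truncated-normal (> 2 um), each
greedily calibrated (resample one, accept if the first two sample
moments move closer to target) within a configurable iteration budget;
a network whose moments remain off target raises a calibration error
naming the statistic.

Two modelling points deserve emphasis. First, vessel length is an
anatomical attribute *decoupled* from the straight-line node distance:
capillaries are tortuous, and the published length moments are far
larger than the inter-node spacing implied by the density. Second,
only the first two moments of the length and diameter distributions
are constrained — the full experimental histograms are not — so the
generated beds are one defensible realization of the published
statistics, not a reconstruction of any particular tissue sample. A
documented consequence (see Limitations) is that the gamma length law
puts non-trivial mass on very short segments, which widens the
conductance distribution.

On the quoted cube volume: the source describes the networks both as
250 um cubes and as having volume 1/4 mm^3 (a 630 um cube). These are
inconsistent; the 250 um edge is adopted because the stated density
then gives ~121 vessels, matching the quoted "approximately 125
vessels", while a 1/4 mm^3 cube would contain ~1930.

## Flow

Each vessel is a Poiseuille resistor with conductance
g = pi d^4 / (128 mu(d) L), where mu(d) is the apparent blood
viscosity of the empirical Pries law at the fixed discharge
haematocrit of 0.45. Both published variants are implemented: the
in-vitro (glass tube) fit and the in-vivo fit, which absorbs the
endothelial surface layer and is substantially higher in the capillary
range (relative viscosity ~4.8 vs ~1.3 at 6 um). The *in-vivo* law is
the default: the boundary condition of the reference experiments
(1000 Pa between the arteriole-capillary and capillary-venule
junctions) was calibrated to produce CBF near 50-60 ml/100 ml/min, and
on 20 generated networks the in-vivo law yields an ensemble mean CBF
of ~47 at 1000 Pa, whereas the in-vitro law yields ~160. Plasma
viscosity defaults to 1.2 mPa s (standard human value; it only scales
the time axis).

Inlets are held at delta_p, outlets at 0, and interior pressures solve
the weighted graph Laplacian system (sparse Cholesky). Edges carrying
less than `flow_tolerance * Q_in` (default 1e-12) are classified
*dead*: they contribute neither to the flow DAG nor to blood volume or
residue — the analytical framework would assign them unbounded transit
times. After occlusion, connected components containing no boundary
node have no defined pressure and physically no flow; by default their
edges are likewise classified dead (`on_floating = "dead"`), with a
strict mode available that errors instead. Flow linearity in delta_p
is exploited by `rescale_pressure()`, which rescales an existing
solution without re-solving; the residue function correspondingly
contracts its time axis exactly, R_{c dP}(t) = R_{dP}(c t), so
pressure changes move both gamma time constants equally and leave the
shape parameters untouched.

Units are um, s, Pa internally (flows in um^3/s); the clinical
conversions CBF = Q_in / V_cube * 6000 (ml/100 ml/min),
CBV = 100 * sum(live V) / V_cube (ml/100 ml) and MTT = sum(live V) /
Q_in (s) happen only at reporting, and satisfy MTT * CBF = 60 * CBV.

## Gamma-mixture characterization

h(t) is characterized as a mixture of 1-3 gamma densities with weights
k_i summing to 1, shapes alpha_i > 1 (so h(0) = 0) and time constants
beta_i > 0; the corresponding residue model is the mixture survival
function, evaluated via the upper regularized incomplete gamma
function (`pgamma(lower.tail = FALSE)`). The mixture mean
sum(k alpha beta) is the MTT; the mixture s.d. is the fitted CTTH.

Fitting (`fit_mixture()`) is unweighted least squares of the mixture
survival against samples of R(t), with constraints enforced by
reparameterization (softmax weights, log transforms with alpha floored
at 1 + 1e-6 and capped at 1e6 — beyond which the component is already
an effective delta) and minimized by Levenberg-Marquardt from 20
seeded moment-matched-plus-jitter starts; the best-RSS start wins and
components are reported sorted by beta ascending (beta_1 fast,
beta_2 slow), which fixes label switching. The default sampling grid
runs from 0 to max(40, 1.5 * t[R = 1e-3]) seconds in 0.05 s steps:
it resolves the fast decay while covering the tail down to a
thousandth of the initial value; tying the grid to the full support
would waste most samples on the near-stagnant tail. Because the RSS
depends on this grid, absolute RSS values are comparable only within a
fixed grid; across studies only orderings (e.g. bigamma < monogamma)
are meaningful.

CTTH is reported twice: `ctth_raw`, the exact s.d. of the analytical
h(t) atoms, and `ctth_fit`, the s.d. of the fitted bigamma. They
answer different questions: the raw second moment is dominated by
near-stagnant vessels carrying < 1% of the tracer mass, while the
fitted value reflects the bulk shape of the distribution that a
characterization-based analysis (including the reference results,
whose tabulated quantities are all fit parameters) actually sees.

## The ensemble study

`run_ensemble()` generates n = 20 networks, runs each healthy and with
20% of vessels removed uniformly at random (paired on the same parent
network and seed), solves at 1000 Pa, computes R(t), h(t), CBF/CBV/MTT
and both CTTH estimates, fits mono- and bigamma models, and summarizes
with per-condition means, s.d.s, medians and quartiles plus two-sided
paired t-tests per quantity (p = 1 is reported when the paired
differences are identically zero, where the t statistic is undefined).
Networks whose occlusion severs every inlet-outlet path are dropped
from the pairing and counted, not fatal. Decay landmarks are
operationalized as the first times R falls to 0.1 and to 0.01
(`time_to_R01`, `time_to_R001`).

These problem sizes — 20 networks of ~121 vessels, 1e5 Monte-Carlo
particles in the oracle checks, 20 fit starts on ~800-point grids —
are the defaults throughout the package, its tests, and the
acceptance script.

## What the generator does and does not emulate

It emulates: the published morphometric moments, boundary junction
counts, tortuosity (length decoupled from geometry), the
diameter-dependent apparent viscosity, and random focal occlusion. It
does not emulate: arteriolar/venular trees (capillary bed only),
vessel curvature, haematocrit heterogeneity and phase separation at
bifurcations, axial diffusion, tracer exchange with tissue, flow
regulation (pericytes), or the full experimental length/diameter
histograms. Passing ensemble tests therefore demonstrate fidelity to
the published summary statistics under these assumptions, not to any
real tissue.

## Known limitations

* Healthy-side ensemble statistics reproduce the reference values
  (CBF ~47 vs 50; fitted CTTH ~2.9 vs 2.35; decay to R = 0.01 in
  ~18 s vs 10-20 s; ~121 vessels vs ~125). Under 20% occlusion this
  implementation degrades *more* than the reference: CBF drops ~60%
  rather than ~40%, and the fitted CTTH roughly doubles rather than
  rising by ~40%. The likely cause is structural: with only the
  published moments to constrain it, the generator's gamma length law
  admits very short high-conductance segments and its opposite-face
  boundary placement makes through-paths long series chains, so random
  removal bites harder than in the (unpublished) reference
  construction. The discrepancy is reported as-is.
* The network-to-network CBF spread (s.d. ~24 at the defaults) is
  larger than the reference (~9.5), for the same structural reasons.
* Fitted beta_2 under occlusion is heavy-tailed across networks (the
  slow component occasionally chases the stagnant tail), which
  inflates its paired-test variance.
* Near-stagnant vessels make the raw h(t) support extremely long;
  quantities defined through the raw second moment should be
  interpreted with this in mind (use `ctth_fit` for comparisons with
  characterization-based analyses).

## Reproducibility

Every stochastic step (generation, occlusion, particle tracking, fit
multistart) takes an explicit integer seed and restores the caller's
RNG state; identical (configuration, seed) pairs give byte-identical
serialized networks and identical pipeline rows. The paired design
reuses the generation seed for the occluded arm so both conditions
share the parent network.
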