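# capres

Analytical residue functions for cerebral capillary networks.

`capres` is for researchers modelling cerebral microvascular perfusion
and tracer kinetics. It answers the question: *given an explicit
capillary network, what residue function — the quantity perfusion MRI
tries to estimate by deconvolution — does it actually produce, and how
does that change when the network is damaged?*

The package

* **generates** random capillary beds in a tissue cube matching human
  cortical morphometry (vessel density 7718 mm⁻³, connectivity 3.22,
  length 59.71 ± 51.61 µm, diameter 6.24 ± 1.30 µm; 3 arteriole inlets
  and 2 venule outlets on opposite faces of a 250 µm cube),
* **solves** steady Poiseuille flow with the empirical
  diameter-dependent apparent blood viscosity (Pries law, in-vivo or
  in-vitro variant) at haematocrit 0.45,
* **computes the exact residue function** `R(t)` of the perfused bed.
  Each vessel delays tracer by its transit time `T = L/U = V/Q`, so a
  single vessel has a rectangular `R(t)`; for a network, `R(t)` is a
  finite sum of rectangles — one per vessel per upstream pathway, with
  height given by the product of flow-split fractions along the
  pathway and width equal to the vessel transit time. The sum is
  assembled exactly (breakpoints, no time grid) by dynamic programming
  over the flow-directed acyclic graph, and `h(t) = -dR/dt`, MTT and
  CTTH (the s.d. of transit times) follow directly,
* **characterizes** `R(t)` with gamma mixtures
  `h(t) = Σ kᵢ Gamma(αᵢ, βᵢ)` (Σkᵢ = 1, αᵢ > 1), fitted by
  constrained Levenberg–Marquardt least squares with seeded
  multistart, and
* **orchestrates** the paired ensemble experiment: 20 networks,
  healthy versus 20 % randomly occluded, at a 1000 Pa
  arteriole-to-venule pressure difference, with summary statistics and
  paired t-tests.

Independent oracles — explicit pathway enumeration and Monte-Carlo
particle tracking — ship with the package and back every analytical
claim in the test suite.

## Worked example

```r
library(capres)

net <- generate_network(seed = 5)
net
#> <vessel_network> 75 nodes, 121 vessels in a 250 um cube
#>   inlets: 3, outlets: 2
#>   density 7744 mm^-3, connectivity 3.23, length 59.7 +/- 51.6 um, diameter 6.24 +/- 1.30 um

sol <- solve_flow(net, delta_p = 1000)   # Pa
sol
#> <flow_solution> dP = 1000 Pa, Q_in = 1.385e+05 um^3/s (117 live / 121 edges)
#>   CBF 53.2 ml/100ml/min, CBV 1.46 ml/100ml, MTT 1.642 s

R <- network_residue(sol)
R
#> <residue_function> 1827 breakpoints, support [0, 39.77] s, integral (MTT) 1.642 s

transit_time_distribution(R)
#> <transit_time_distribution> 1826 atoms, total mass 1.000000
#>   MTT 1.642 s, CTTH 2.126 s

residue_time_below(R, 0.01)
#> [1] 10.54

fit_residue(R, n_components = 2, seed = 5)
#> <mixture_fit> 2 components, RSS 0.03878 over 801 samples
#> <gamma_mixture>
#>   k=0.755 alpha=6.010 beta=0.1594 s
#>   k=0.245 alpha=1.838 beta=1.901 s
#>   MTT 1.581 s, CTTH 1.714 s
```

Reading the numbers: this 121-vessel bed perfuses at 53 ml/100 ml/min
— in the healthy human range the 1000 Pa boundary condition was
calibrated for — and holds 1.46 % blood by volume, so tracer resides
for 1.64 s on average. The exact `R(t)` is a staircase of 1827 steps
whose integral reproduces the MTT to machine precision; it decays to
1 % of its initial value within ~10.5 s. The bigamma characterization
splits transit times into a fast pathway pool (β₁ ≈ 0.16 s, ~76 % of
tracer) and a slow one (β₂ ≈ 1.9 s), the shape a perfusion analysis
would see.

Occluding 20 % of the same network's vessels and re-solving:

```r
occ <- occlude(net, fraction = 0.2, seed = 5)
haemodynamics(solve_flow(occ))$CBF
#> [1] 17.7
```

CBF falls and (across the ensemble) transit times spread out — the
residue function decays more slowly and its slow gamma component
stretches, the signature of reduced collateral pathways.

The full paired study is one call:

```r
res <- run_ensemble(n = 20, occlusion = 0.2, seed_base = 1)
res$aggregate   # means, s.d., medians, quartiles, paired t-tests
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/capres` (subcommands `generate`, `occlude`, `stats`,
`solve`, `residue`, `fit`, `ensemble`); run it with `Rscript` or make
it executable.

## Further reading

The methods vignette (`vignettes/capres-methods.Rmd`) documents the
transport model and its assumptions, the sum-of-rectangles
construction and its numerical tolerances, the generator's calibration
strategy, the viscosity-law choice, the fitting grid, and known
limitations of the synthetic beds.
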