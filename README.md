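# sirw — self-interacting random walks with a Lennard-Jones memory

`sirw` simulates a growing random walk in continuous 3D space whose steps
remember where the walker has been. It is aimed at people studying polymer
and protein-folding physics with minimal models: the walk is a coarse
polymer chain (one visited position per monomer / Cα), and the question it
answers is how much structure — collapse, and in particular *helix*
formation — emerges from nothing but an isotropic pair attraction and
thermal noise, with no bending or torsion potential.

## Model

The walker starts at the origin and makes `N` moves of fixed length `d0`
(the distance unit). At each step it considers a large, near-uniform set of
candidate directions on the sphere of radius `d0` (default 2000; the
published-scale setting is 15,212 geodesic vertices) and draws one with
Boltzmann probability

    P(n -> n+1)  ∝  exp( -(U_{n+1} - U_n) / kB T ),        kB = 1

where `U_n` is the walker's total pair energy with *all* previously visited
positions under the Lennard-Jones potential

    u(r) = ε [ (r0/r)^12 - 2 (r0/r)^6 ]

with well depth `ε` and equilibrium distance `r0` (minimum `-ε` at
`r = r0`). Trajectories are scored by the radius of gyration `Rg` and a
helix fraction `H`: a sliding window of `K = 10` consecutive turns counts as
one helical turn when every local turn has the same handedness (sign of the
scalar triple product of consecutive connections) and the turning angles sum
to more than 2π; `H` is the fraction of positions covered by at least one
qualifying window.

Depending on `r0` and `T` the model produces compact globules, extended
strings, random coils — and, in three narrow windows of `r0` near 1.52,
1.69 and 1.82, helices. At `r0 = 1.52` the chain shows a coil → globule
transition near `kB Tc ≈ 1.25 ε` on cooling and a globule → helix
transition near `kB Tc ≈ 0.05 ε`; both transition temperatures scale
linearly in `ε` (`kB Tc = λ ε`), which `fit_lambda()` quantifies.

## Worked example

```r
library(sirw)

p <- walk_params(temperature = 0.01, epsilon = 1, r0 = 1.52, n_steps = 50,
                 n_directions = 2000, seed = 42)
tr <- simulate_walk(p)
tr
#> SIRW trajectory: 51 positions (T=0.01, epsilon=1, r0=1.52, seed=42)
#>   Rg = 5.5296, final U = 123.9297
helix_fraction(tr$positions)
#> Helix annotation: H = 1.000 (51 of 51 positions), handedness = right, 4.54 steps/turn
steps_per_turn_axis(tr$positions)   # azimuthal count about the helix axis
#> [1] 4.14

en <- run_ensemble(p, n_runs = 100)
en
#> SIRW ensemble: 100 runs at T=0.01, epsilon=1, r0=1.52 (0 trapped)
#>   <Rg> = 5.3118 (sem 0.0792)
#>   <H>  = 0.9433 (sem 0.0206)
#>   <E>/position = 121.6225
```

A cold walk at `r0 = 1.52` is a right-handed (or, equally often,
left-handed) helix: every position lies in a qualifying turn window
(`H = 1`), with ~4 steps per turn about the helix axis. Over 100 independent
runs the ensemble helix fraction is ≈ 0.94 — nearly every run folds into the
same helix. The large positive per-position energy is dominated by the
constant bonded-neighbor repulsion (bonds sit at distance `d0 = 1 < r0`);
it cancels out of every step decision.

`write_xyz()` / `write_pdb()` export trajectories (the PDB writer renders
the walk as a Cα trace at 3.8 Å per step), `read_positions()` brings in
external XYZ/PDB traces so the same metrics can be run on real protein
Cα chains, and `sweep_temperature()`, `estimate_transition_temperature()`,
`fit_lambda()` and `phase_diagram()` automate the phase analysis.

A command-line front end ships in `exec/sirw`:

```sh
Rscript exec/sirw simulate --temperature 0.01 --r0 1.52 --seed 7 --out run.xyz
Rscript exec/sirw metrics --in run.xyz
Rscript exec/sirw sweep --grid-log 0.001,100,21 --r0 1.0 --runs 100 --out sweep.csv
```

`--paper` switches any subcommand to the published-scale settings (50 steps,
15,212 geodesic directions, 1000 runs).

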