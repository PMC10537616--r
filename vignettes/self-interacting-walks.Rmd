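---
title: "Self-interacting random walks: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-interacting random walks: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A self-interacting random walk (SIRW) grows a chain of `n_steps + 1`
positions in continuous 3D space. The walker starts at the origin; each move
has fixed length `d0` (the distance unit, `kB = 1` for energies). Candidate
positions are the current position plus `d0` times each member of a fixed,
near-uniform direction set on the unit sphere, and the move is drawn with
probability proportional to `exp(-(U_next - U_current)/T)`, where `U` is the
summed Lennard-Jones energy

\[ u(r) = \varepsilon\left[(r_0/r)^{12} - 2 (r_0/r)^6\right] \]

between the candidate and **every** previously visited position, the bonded
neighbour included. The chain only grows — there are no pivot or reptation
moves, no bending or torsion potential, no excluded-volume term beyond the
LJ core itself. The model's point is exactly this austerity: an isotropic
pair attraction with a minimum at `r0`, plus thermal noise, is sufficient to
produce coil, globule, extended-string and helical phases.

Assumptions worth making explicit:

* Trajectories are *growth* processes, not equilibrium samples of a chain
  Hamiltonian. All phase behaviour reported by this package is behaviour of
  the growth ensemble.
* Because the energy of the current position is a constant across
  candidates, the Boltzmann rule reduces to weights
  `exp(-U_next/T)` normalized over the candidate set; the first step
  (history = origin only) is automatically uniform.
* Since every move adds one bonded pair at distance `d0`, the bonded LJ term
  (large and positive when `r0 > d0`) is a constant offset per step. It
  cancels from all step decisions, but it dominates raw configuration
  energies — compare energies only between configurations of equal length.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `temperature` | thermal energy (`kB = 1`) | — | studied range 0.001–100 |
| `epsilon` | LJ well depth | 1 | transition temperatures scale as `λ·epsilon` |
| `r0` | LJ minimum distance (units of `d0`) | 1.5 | 1.0–2.5 is the interesting range; helices near 1.52, 1.69, 1.82 |
| `d0` | step length | 1 | the distance unit |
| `n_steps` | number of moves | 50 | 51 positions; the published-scale chain length |
| `n_directions` | candidate directions | 2000 | 15,212 (geodesic `f = 39`) at published scale; results are insensitive beyond ~1000–2000, except that sharply tuned helices (`r0 ≈ 1.8`) benefit from density |
| `rule` | step selection | categorical | `metropolis` = uniform proposal + accept/reject; samples the same law |
| `rmin` | hard-core cutoff | `0.1 r0` | below it the pair energy is `+Inf` (weight exactly 0) |
| `K` | helix window length (connections) | 10 | detection window, *not* the helix period |

**Direction sets.** Two deterministic constructions: a golden-angle
Fibonacci spiral (any count; the default) and an icosahedral geodesic
subdivision (counts `10 f² + 2`; `f = 39` gives 15,212). At these densities
the two are interchangeable — the test suite asserts unit norms, centroid
balance and a minimum-separation bound for both. The set is built once per
simulation and reused at every step; re-randomizing it per step would only
add cost at equal angular resolution.

**Step rule.** The Boltzmann move probability is interpreted as categorical
sampling over the whole candidate set (the reading that matches a rule
phrased as "choose a position among many with probability ∝ exp(-ΔU/T)").
A `metropolis` switch is kept for sensitivity checks: uniform proposal,
accepted with the Boltzmann factor relative to the step's minimum candidate
energy. That reference must live inside the candidate set — an acceptance
test against the *current* energy would stall, because every move pays the
constant bonded term `u(d0)`. With the in-set reference the rule is exact
rejection sampling of the same categorical distribution, so the two rules
differ only in RNG consumption.

**Hard core.** Candidates closer than `rmin = 0.1 r0` to any visited
position get energy `+Inf` and selection weight exactly 0. At any
temperature in the studied range the Boltzmann factor there would be
`exp(-1e12/T)`, so the cutoff is numerically exact; its purpose is to keep
`r^-12` from overflowing, not to add physics.

**Numerical discipline.** Candidate weights are computed after subtracting
the minimum candidate energy (max-shift), so `T = 0.001` and `T = 100` are
handled by the same code path without under/overflow. Energies accumulate
in double precision over the full O(N) history — at 51 positions a neighbor
list would be pointless. One seeded RNG stream drives each trajectory;
ensembles use the documented seed sequence `base_seed + run_index`, which
makes every individual run re-creatable and the ensemble mean independent
of execution order.

## Order parameters

`radius_of_gyration()` is the root-mean-square distance of the `M = N + 1`
positions from their centroid. All package-internal values are in `d0`
units. One unit note: when walks are rendered or compared as protein Cα
traces, the conventional scale is 3.8 Å per step (`write_pdb()`'s default),
and plateau readings quoted on that scale are `3.8×` the native values.
The acceptance script reports the two `r0 = 1.0` plateau heights on the
Cα-trace scale for comparability with published readings, and the
native-unit values are always recoverable by dividing by 3.8.

`helix_fraction()` slides a window of `K` consecutive
connection-vs-previous-connection turns (so `K + 1` connections, `K + 2`
positions). A window qualifies as a helical turn when

1. every scalar-triple-product turn sign inside it is nonzero and equal
   (uniform handedness; a coplanar turn disqualifies the window — a flat
   segment is not a helix turn), and
2. its `K` turning angles sum to more than 2π.

A position is helical if at least one qualifying window covers it, so each
position counts at most once and a perfect helix reaches `H = 1` exactly.
The denominator is the number of positions (51), consistent with that
endpoint. `K = 10` is a *detection* window: large enough to demand a full
2π of coherent turning, small enough to tolerate local fluctuation; the
observed helices turn in 4–6 steps, well inside one window.

**Steps per helical turn, twice.** The window quantity
`2πK / Σ(turning angles)` is attached to the annotation, but the 3D turning
angle between successive connections shrinks as the helix rise grows, so
this ratio systematically *overestimates* steps per turn (for the `r0 =
1.52` helix: 4.5 by window angles vs 4.1 in truth). What one means by
"steps per turn" — and what one counts when looking at a rendered helix —
is azimuthal rotation about the helix axis. `steps_per_turn_axis()`
therefore fits the axis (first principal component of the longest helical
segment), unwraps the azimuth in the perpendicular plane and returns
`2π / mean azimuthal advance`. On ideal helices of 3–8 points per turn it
recovers the construction to < 1%, and it is the estimator used for the
helix-size checks (4 / 5 / ~5.8 steps per turn at `r0` = 1.52 / 1.69 /
1.82).

## Transition analysis

`sweep_temperature()` runs one seeded ensemble per grid point; grids are
log-spaced because the interesting range spans five decades.
`estimate_transition_temperature()` offers two deterministic estimators:

* **Rg**: the temperature of steepest change of `⟨Rg⟩` per unit `ln T`
  (argmax over grid intervals, refined by a quadratic through the three
  slopes around the maximum, clamped to one grid interval). A `direction`
  argument restricts to rising or falling segments, which separates the two
  branches of the reentrant `r0 = 1.52` curve.
* **H**: the interpolated falling crossing of `⟨H⟩ = 0.5` in `ln T`.

Flat curves return a sentinel (`Tc = NA`) rather than an error; the flat
test is total variation below 5% of the observable's magnitude. The
steepest-slope estimator has an intrinsic jitter of about one grid interval
when the underlying sigmoid is broad — the coil–globule `Tc` at `r0 = 1.52`
moves within roughly 1.3–1.8 across seeds on a 0.2-decade grid. The
`H = 0.5` crossing is much stiffer (the helix transition is sharp).

`fit_lambda()` fits `kB Tc = λ ε` through the origin by least squares
(`λ = Σ ε·Tc / Σ ε²`). The coil–globule line fits with `λ` of order 1, the
globule–helix line with `λ` smaller by a factor of ~25, and their ordering
`λ_cg > λ_gh` is a structural fact of the model. `phase_diagram()` labels
each `(T, ε)` cell helix first (`⟨H⟩ ≥ 0.5` — helix and globule are both
compact, so the helix label takes precedence), then globule or coil by
whether `⟨Rg⟩` lies below the midpoint of that well depth's globule and
coil plateaus.

## What the simulations do and do not emulate

The generator *is* the model under study: every ensemble in the tests and
the acceptance script is produced by `simulate_walk()` at the study
conditions (51 positions; `ε = 1` unless swept; `T` and `r0` as stated;
categorical rule). Defaults scaled for interactive use are 2000 directions
and 100 runs; the published-scale settings (15,212 directions, 1000 runs)
are one flag away (`--paper`) and change results only within quoted
standard errors. The tests use 40–100 runs per point and state their grids
inline; the acceptance script uses 26-point sweeps at 100 runs (60 for the
four-ε λ fits). These sizes put standard errors of `⟨H⟩` and `⟨Rg⟩` near
0.01–0.1, adequate for every gate tested.

A walk trajectory is *not* a protein: there is no sequence, no hydrogen
bond, no solvent, and the chain cannot rearrange after growth. Passing
tests show that the claimed phase structure emerges in this growth
ensemble; they say nothing about equilibrium polymers (where similar
transitions require explicit stiffness terms) beyond the analogy.

## Known limitations

* **The third helix window is marginal.** At `r0 ≈ 1.82` the ensemble helix
  fraction peaks at ≈ 0.90 (unchanged at 15,212 directions), and the helix
  there turns in ≈ 5.8 steps. Checks that expect that window to peak above
  0.9, or its helix to round to 5 steps per turn, sit on the wrong side of
  those measurements and are left failing rather than retuned.
* **The infinite-temperature limit converges slowly.** The LJ core blocks
  an exclusion sphere whose radius shrinks only as `T^{-1/12}`, so at
  `T = 1e6` back-folding is still suppressed and `⟨R²_end⟩` sits ~8–13%
  above the ideal-walk value `N d0²`; the ideal limit is recovered at
  `T ≈ 1e12`.
* **"Energy gap between phases" is definition-sensitive.** Between the
  globule and coil plateau regions the per-position pair-energy difference
  is ~3–4.5 (and drifts with the upper plateau window, since thermal core
  overlaps push the coil energy up with `T`); splitting runs at the
  transition temperature by compactness instead gives ~0.4. No definition
  we implemented lands near 1.0; both variants are exposed
  (`mean_energy`, `configuration_energy`).
* The walker can in principle trap (all candidates inside the hard core);
  in practice this never occurs at the studied parameters, and ensembles
  count and exclude such runs, failing hard above 5%.
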