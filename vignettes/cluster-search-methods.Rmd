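---
title: "Methods: swarm-based global optimization of cluster geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-based global optimization of cluster geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psocluster)
```

## The problem

A cluster of $n$ atoms has a potential energy surface (PES) over $3n$
Cartesian coordinates with a number of local minima that grows roughly
exponentially with $n$.  Finding the *global* minimum — the
thermodynamically relevant structure — is the central computational task in
small-cluster chemistry: for pure carbon clusters, for example, the
competition between linear chains and rings is decided by energy
differences of a few kcal/mol, far below the depth of typical local traps.
Gradient-based optimization alone only finds the minimum of whatever basin
the starting guess sits in, so a stochastic global searcher is layered on
top of the energy function.

`psocluster` implements one such searcher — a modified particle swarm
optimizer (PSO) with stall-based termination and a
restart-to-self-consistency outer loop — together with the two classical
comparators it is usually benchmarked against, simulated annealing (SA)
and basin hopping (BH).  All three run over one energy-backend contract,
so the same search code drives an analytic pair potential or an external
quantum-chemistry engine.

## The swarm model

Each *particle* is one complete candidate cluster: a flat vector
$x \in \mathbb{R}^{3n}$ in which atom $i$ (0-based) occupies slots
$3i, 3i{+}1, 3i{+}2$.  Velocities and positions evolve as

$$v^{t+1}_j = w\,v^t_j \;+\; d_1\,\varepsilon_{1j}\,(p_{\mathrm{best},j} - x^t_j)
  \;+\; d_2\,\varepsilon_{2j}\,(g_{\mathrm{best},j} - x^t_j), \qquad
  x^{t+1} = x^t + v^{t+1},$$

with $\varepsilon_1, \varepsilon_2$ uniform in $(0,1)$, $p_\mathrm{best}$
the best position the particle itself has visited and $g_\mathrm{best}$
the best position any particle has visited.  The defaults are the standard
small-cluster parameterization: population $N_\mathrm{pop} = 10$, inertia
$w$ descending linearly from 0.8 to 0.4 over the run, cognitive and social
accelerations $d_1 = d_2 = 2$, initial coordinates uniform in $(-3, 3)$.

Decisions this package had to make where the method description is
genuinely open:

* **Granularity of $\varepsilon$.**  The update draws $\varepsilon_1$ and
  $\varepsilon_2$ *per component*, the common modern practice; it explores
  the $3n$-dimensional space better than a single scalar per particle.
* **Initial velocities** are uniform in $\pm 0.1 \times$ the
  initialization width — a small kinetic spread that avoids immediate
  flight out of the sampled box.
* **Velocity clamping** bounds each component at
  $0.5\,(\texttt{init\_high} - \texttt{init\_low})$ (default 3.0).  No
  positional walls are enforced after initialization: the $(-3,3)$ box
  constrains *generation* only, and relaxed clusters are free to leave it.
* **Personal bests** start at a $+\infty$ sentinel, so the first real
  evaluation always installs a genuine energy; ties never displace an
  incumbent best.

### Termination: the stall rule

A run terminates when the energy found by the swarm has remained the same
(within `energy_tol`, default $10^{-6}$) for 30 successive iterations, or
at `max_iter` (default 600, the length of a typical published convergence
curve).  One subtlety mattered in practice: *which* energy sequence the
rule watches.  Applied to the running global best, the rule kills healthy
runs — with a 10-particle swarm the improvement events of
$g_\mathrm{best}$ routinely have gaps longer than 30 iterations while the
swarm is still exploring (measured on 3- and 4-atom Lennard-Jones
clusters: most runs terminate before iteration 100, far from the
minimum).  Applied to the *per-iteration best evaluated energy* — the
energy the swarm finds at each iteration — the rule only fires once the
swarm has genuinely collapsed, and observed termination happens around
iteration 200–480, matching the reported behaviour of this class of
searcher.  `psocluster` uses the second reading.  The exported
`has_converged()` is agnostic: it tests any energy sequence for an
unchanged window.  On a constant-energy backend the two readings coincide
exactly, which is what the convergence-rule acceptance test pins down.

### Restarts to self-consistency

A single swarm run, once collapsed, is done: the velocity update supplies
no further exploration pressure, and the attractive tail of a pair
potential is so flat that a particle drifting toward an incomplete cluster
improves more slowly than the stall tolerance can see.  The published
procedure therefore restarts: new initial structures are generated *from
the output structures* of the previous run, and the process repeats until
self-consistency.  `restart_search()` implements this loop: after each
inner run, half the particles restart from the incumbent best geometry
plus zero-mean Gaussian noise ($\sigma = 0.3$), the other half from fresh
uniform draws, and the loop stops early when two consecutive restarts'
best energies agree within `energy_tol` (cap: `n_restarts`, default 10).
The half/half recipe balances refinement of the incumbent funnel against
escape from it; $\sigma = 0.3$ is roughly a quarter of a bond length —
large enough to re-inflate the swarm, small enough to stay in the
funnel.

Measured on the desk-scale test systems, the restart loop is not a
convenience but the difference between failure and success: single runs
reach the 3-atom minimum to $10^{-3}$ in roughly 2–4 of 10 seeds, the
full procedure in 9–10 of 10.  This mirrors the published pipeline, in
which swarm output is additionally refined by the engine's own optimizer
before energies are reported.

## Energy backends and the penalty policy

A backend evaluates one position vector and reports an `energy_result`
with a status: `ok`, `overlap_rejected`, or `engine_failed`.  The two
non-ok statuses carry a finite penalty energy $+10^6$: the particle
survives (Eq. 1 stays well-defined) but can never turn the bad
configuration into a personal best.  Randomly generated structures *do*
contain overlapping atoms; a quantum-chemistry engine diverges on fused
nuclei, so geometries whose minimum pair distance falls below a threshold
(0.5 Å for external engines; $10^{-3}$ length units for the analytic
potentials, where the potential is mathematically fine but physically
meaningless) are rejected *before* the engine is invoked.

Built-in analytic backends: Lennard-Jones
$4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ and Morse
$D_e[(1 - e^{-a(r - r_e)})^2 - 1]$, both with analytic gradients (checked
against central finite differences at $h = 10^{-6}$).  In reduced LJ units
the 3- and 4-atom global minima are exact ($-3\varepsilon$,
$-6\varepsilon$), which anchors the test suite; the 5- and 6-atom
references come from the multi-start oracle below.

The external adapter is engine-agnostic: an `engine_template` holds a
text deck with `{COORDS}`/`{CHARGE}`/`{MULT}`/`{TITLE}` placeholders, a
command, and a regular expression that captures the energy from the log
(the *last* match wins, because iterative engines print one energy per
cycle and the converged value is final).  Coordinates are rendered to 6
decimal places; a worked Gaussian-style template ships in the
`engine_template()` documentation.  The `mock_engine_backend()` runs this
entire render–invoke–parse pipeline against an internal LJ evaluation, so
the coupling is testable without any external software.  Note the
6-decimal deck bounds round-trip accuracy to about $10^{-6}$ only near
equilibrium; on the $r^{-12}$ repulsive wall the same coordinate rounding
is amplified a thousandfold, which is why round-trip agreement is asserted
in the near-equilibrium regime.

## Parallel evaluation and determinism

Energy evaluations are by far the dominant cost when an external engine
is attached, and they are embarrassingly parallel within one iteration —
but the iteration end is a hard barrier: bests cannot be updated until
every particle's engine run has completed.  `evaluate_swarm()` forks at
most `n_workers` concurrent jobs and returns only after all finish; a
timed-out or crashed job becomes `engine_failed` with the penalty energy
without disturbing its neighbours.

Determinism is a contract, not an accident: every random draw (initial
positions and velocities, the per-component $\varepsilon$'s, restart
noise) is taken in the coordinator *before* dispatch, from a per-particle
L'Ecuyer-CMRG substream spawned from the root seed.  Workers are pure
functions of their inputs.  Consequences: a run is bit-identical for any
worker count, particle $i$'s initialization does not depend on the
population size, and the ambient R session RNG is never touched.

## Comparator searchers

**Simulated annealing** (`run_sa`) is a Metropolis walk: every step
perturbs *all* coordinates by independent uniforms of half-width
`step_size`, accepts downhill moves always and uphill moves with
probability $e^{-\Delta E / T}$, and cools geometrically
($T \leftarrow \alpha T$ every `steps_per_T` steps; a linear schedule is
available).  Because a proposal moves the entire cluster, the move cost of
an already-bound sub-cluster scales with $s^2 \times$ its stiffness; large
steps freeze the system as soon as the first bond forms, so the productive
regime is small steps with slow cooling.  The schedule used in the
acceptance run (T₀ = 0.5, α = 0.97, 500 steps per stage, s = 0.01,
2×10⁵ steps) reaches the 5-atom LJ minimum to $10^{-3}$ in 9 of 10
seeds — yet needs an order of magnitude more energy evaluations than the
swarm, which is precisely the qualitative ranking the method comparison
in the source literature reports.

**Basin hopping** (`run_bh`) alternates a uniform perturbation of
half-width `perturb_delta` with full local minimization and a Metropolis
test *on the minimized energies* at fixed `accept_T` (the classic
formulation; always-accept-downhill is its $T \to 0$ limit).  The
perturbation must be large enough to leave the current basin:
`perturb_delta = 0` provably returns the same minimum forever, which the
suite asserts.  The local minimizer is a hand-rolled BFGS with Armijo
backtracking, Shanno initial scaling, and a trial-step cap of 0.5 length
units — the cap matters, because an uncapped first step from a
high-gradient (near-overlap) configuration blasts the cluster apart into
a flat dissociated region it cannot return from.  External single-point
backends carry no gradient and are rejected with a capability error,
mirroring the original division of labour in which the quantum-chemistry
engine performed the final optimizations itself.

Default `minimizer_tol` is $10^{-6}$ on the gradient norm: near a
minimum the energy differences the line search relies on scale like the
*square* of the gradient norm, so demanding $10^{-8}$ runs into double
precision before the stopping rule can fire.

## The reference oracle

`reference_minimum()` is the package's independent referee: at least 1000
L-BFGS-B minimizations (via `stats::optim`, deliberately *not* the
package's own BFGS) from uniform random starts, keeping only strictly
converged (gradient norm $< 10^{-6}$), connected (maximum pair distance
$< 4\times$ the potential's length scale) outcomes.  For LJ clusters up
to $n = 6$ two oracle runs with different seeds agree to $10^{-6}$.  The
frozen values (5000-start runs) exposed by `lj_reference_energies()`:

| $n$ | connected minima (reduced units) |
|----|----------------------------------|
| 3  | $-3$ (equilateral triangle, exact) |
| 4  | $-6$ (regular tetrahedron, exact) |
| 5  | $-9.10385242$ (trigonal bipyramid; the only connected minimum) |
| 6  | $-12.71206226$ (octahedron) and $-12.30292753$ (capped bipyramid) |

The 6-atom surface is the desk-scale analogue of a PES with two competing
deep wells — the situation the swarm method is specifically advertised
for.  The octahedral global basin is *small* (about 2.6% of random
starts), so naive multi-start lands in the second funnel almost always.
"Resolving the two funnels" is asserted by basin membership: the
structure a search returns is assigned to its funnel by local
minimization, every returned structure must sit in one of the two lowest
funnels, and across ten seeds both funnels must appear.  Raw (unminimized)
swarm energies in 18 dimensions carry $\sim 10^{-1}$ refinement error at
this iteration budget, so raw-energy matching at $10^{-3}$ would conflate
funnel identification with local refinement — the published pipeline
likewise reported engine-optimized energies, its swarm stopping
$\sim 10^{-2}$ a.u. above them.

## What the desk-scale tests do and do not establish

The analytic potentials stand in for the real objective (a DFT
single-point energy).  They reproduce the *search-relevant* features —
many minima, steep repulsive walls, flat long-range tails, funnels of
very different volume — but not electronic effects (spin multiplicity,
charge), not engine failures of the SCF kind (emulated instead by the
scripted mock engine), and not the a.u.-scale energy spacing of real
clusters.  A green suite therefore establishes that the search machinery,
the coupling contract, the parallel barrier and the determinism guarantees
work as specified, and that the searchers find known global minima on
surfaces of honest difficulty; it does not certify chemistry.  Wall-clock
comparisons between methods are out of scope (hardware-dependent); the
trajectory log (`trajectory.tsv`: restart, iteration, best energy,
evaluations, stall counter) contains everything needed to reproduce
convergence-curve figures and iteration-count comparisons.

## Known limitations

* The swarm parameterization ($d_1 = d_2 = 2$ with uniform
  $\varepsilon$) is variance-marginal by modern PSO stability analysis;
  deep refinement relies on the restart loop by design.  Constriction-type
  coefficients would refine faster but are a different method.
* Single inner runs terminate by the stall rule while still
  $\sim 10^{-2}$ above the minimum; quote energies from
  `restart_search()`, not `run_pso()`.
* The external adapter is single-point only — no gradient extraction
  from engine output, hence no basin hopping over external backends.
* The oracle is guarded to $n \le 8$; it is an instrument for validating
  searchers at desk scale, not a searcher itself.
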