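# psocluster

Stochastic global optimization of small atomic cluster geometries in R.

Small clusters (a handful of atoms) live on potential energy surfaces with
many competing minima — chains versus rings, close-packed versus capped
shapes — separated by energies far smaller than the depth of local traps,
so plain geometry optimization finds whatever basin the guess sits in, not
the global minimum.  `psocluster` layers a population-based stochastic
searcher on top of any energy function: a modified **particle swarm
optimizer** (PSO) with stall-based termination and a
restart-to-self-consistency outer loop, plus the two classical comparators
it is usually benchmarked against, **simulated annealing** and **basin
hopping**.  It is aimed at computational chemists who want a reproducible,
engine-agnostic search driver, and at method developers who want honest
desk-scale baselines.

## The method

Each particle is a complete candidate cluster, encoded as a flat vector
`x ∈ R^(3n)` (atom *i* in slots `3i, 3i+1, 3i+2`).  Velocities and
positions evolve as

    v' = w v + d1 ε1 (pbest − x) + d2 ε2 (gbest − x)
    x' = x + v'

with `ε1, ε2 ~ U(0,1)` per component, `pbest`/`gbest` the personal/global
best positions, inertia `w` descending linearly 0.8 → 0.4, `d1 = d2 = 2`,
population 10, initial coordinates uniform in (−3, 3).  A run terminates
once the energy found by the swarm is unchanged (within `1e-6`) for 30
successive iterations; the full procedure then reseeds a new swarm from
the incumbent best structure (half perturbed, half fresh) and repeats
until two consecutive restarts agree — self-consistency.

Energy evaluation is a pluggable contract: built-in Lennard-Jones and
Morse pair potentials (with analytic gradients) for desk-scale work, and a
file-based adapter that drives any external quantum-chemistry engine
through a templated input deck and a log-parsing pattern.  Swarm
evaluations run in parallel with a hard per-iteration barrier and are
bit-identical for any worker count (all randomness is drawn from
per-particle substreams before dispatch).

## Worked example

Find the global minimum of a 4-atom Lennard-Jones cluster (reduced units;
the known answer is the regular tetrahedron at energy −6 with all six
pair distances `2^(1/6) ≈ 1.1225`):

```r
library(psocluster)
cfg <- swarm_config(seed = 42)          # published defaults: N=10, w 0.8->0.4, d=2,2
res <- restart_search(cfg, lj_backend(), n_atoms = 4)
res
#> <pso+restart search> best energy -5.9999999 after 1702 iterations (converged)
#> restart best energies: -5.0774917, -5.9999999, -5.9999999

res$best_geometry
#> <cluster_geometry> 4 atoms (C)
#> C  -0.613184   1.138336   0.143397
#> C  -0.337957   0.518151  -0.750785
#> C   0.009423   0.213327   0.272117
#> C   0.447923   1.120616  -0.222276

round(sorted_pair_distances(res$best_position), 4)
#> [1] 1.1224 1.1224 1.1224 1.1225 1.1225 1.1225
```

Reading: the first swarm run stalled in a partial structure (−5.08), the
first restart found the tetrahedral funnel, and the second reproduced its
energy to within 1e-6 — self-consistency — so the loop stopped.  The
sorted pair-distance fingerprint identifies the tetrahedron without any
point-group machinery.

Compare the searchers, or check against the brute-force oracle:

```r
run_sa(sa_config(seed = 1), lj_backend(), start = runif(12, -1.2, 1.2))
run_bh(bh_config(seed = 1), lj_backend(), start = runif(12, -1.2, 1.2))
reference_minimum(4, n_starts = 1000)$energy   # -6 (multi-start L-BFGS oracle)
```

## Command line

```sh
Rscript inst/cli/psocluster search inst/extdata/lj3.ini --out runs/lj3
#> pso+restart: best energy -2.99999983 (converged)
Rscript inst/cli/psocluster compare inst/extdata/lj3-compare.ini
#> method  iterations  best_energy  converged   (one row per searcher)
Rscript inst/cli/psocluster oracle --n 5
```

`search` writes `best.xyz`, a tab-separated `trajectory.tsv` (restart,
iteration, best energy, evaluations, stall counter — enough to replot
convergence curves), and a `summary.txt` of key = value pairs.

Wiring a real engine needs only a config pointing at a deck template whose
log prints a parsable total energy; see `?engine_template` for a
Gaussian-style example and `?external_backend` for the scratch-directory
and failure semantics (crashed, timed-out or unparsable runs score a
finite penalty and never abort an iteration).

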