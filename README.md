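# trajspace

Data management for numerical parameter explorations in R.

A parameter exploration samples an *n*-dimensional parameter space with an
ordered set of points and runs a simulation or model once per point; each
*single run* is independent and produces results. Because the point set is
ordered, the sweep traces a *trajectory* through the space — and keeping the
sampled parameters and the produced results together, instead of scattering
them over ad-hoc file hierarchies and hand-rolled naming schemes, is what
this package is for. It targets anyone who runs simulations over parameter
grids or adaptive samples (computational neuroscience being the motivating
field) and wants storage, bookkeeping, parallelisation and reloading handled
by one coherent container.

Three components cooperate:

* **`Trajectory`** — a rooted tree with reserved top-level groups
  `parameters`, `results` and `config`. Leaves are typed containers:
  a *parameter* holds one dimension of the space (a default value, an
  optional exploration range, and a lock that freezes it once a run has
  used it), a *result* holds a named bag of values produced by a run.
  Content is recalled by *natural naming* — dotted queries such as
  `traj$get("results.runs.crun.pattern")` — where unique intermediate
  groups may be elided and `crun` binds to the currently selected run.
  Exploration is declared as `explore(spec)` with equal-length value
  sequences (one entry per run, indices starting at 0), with
  `cartesian_product()` building grid sweeps and `expand()` appending
  points to an already-executed trajectory for adaptive schemes.
* **`RunEnvironment`** — the scheduler. It executes a user model
  (`function(traj, ...)`) once per pending run, serially or on a fork-based
  worker pool, collects returned values as a sorted list of
  `(index, returned)` pairs, books per-run completion and runtime (which is
  what makes crash *resume* possible), writes a full log plus a dedicated
  error log, reports progress with a remaining-time estimate, and — unless
  automatic storing is disabled — persists each run's results right after
  the run.
* **`Hdf5StorageService`** — persistence. The tree maps one-to-one onto the
  group hierarchy of a single HDF5 file (inspectable with any HDF5 tool);
  every stored item carries a `type_tag` attribute so values reload as
  exactly the R kind that was stored. Trajectories reload at three levels —
  `skeleton` (metadata, run table, explored ranges), `structure` (stubs for
  the whole tree) and `full` — and with `auto_load` any naming request that
  misses the in-memory tree is satisfied from disk on the fly.

Bundled example models exercise the whole stack: scalar multiplication,
elementary cellular automata (256 rules, periodic boundaries), a greedy
stochastic optimizer that alternates run and post-processing phases, and a
leaky integrate-and-fire network with delta synapses.

## Worked example

```r
library(trajspace)

f <- file.path(tempdir(), "multiply.h5")
env <- run_environment(trajectory = "multiply", filename = f)
env$traj$add_parameter("x", 1.0, comment = "I am the first dimension!")
env$traj$add_parameter("y", 1.0, comment = "I am the second dimension!")
env$traj$explore(cartesian_product(list(x = c(1, 2, 3, 4), y = c(6, 7, 8))))
outcomes <- env$run(model_multiply)
```

The grid has 12 points, enumerated with the first-listed parameter cycling
fastest: `(1, 6), (2, 6), (3, 6), (4, 6), (1, 7), ...`. `model_multiply`
computes `z = x * y`, stores it as the per-run result `z` and returns it, so
`outcomes` is the sorted pair list

```
(0, 6.0) (1, 12.0) (2, 18.0) (3, 24.0) (4, 7.0) (5, 14.0)
(6, 21.0) (7, 28.0) (8, 8.0) (9, 16.0) (10, 24.0) (11, 32.0)
```

Analysis typically happens in a separate session against the file alone:

```r
traj <- load_trajectory(f, level = "skeleton", auto_load = TRUE)
traj$get("results.runs.run_00000002.z")   # 18, loaded from disk on demand
head(traj$run_table(), 3)
#>   index         name completed failed runtime_seconds         finished_at
#> 1     0 run_00000000      TRUE  FALSE           0.002 2026-09-24T02:49:09
#> 2     1 run_00000001      TRUE  FALSE           0.015 2026-09-24T02:49:10
#> 3     2 run_00000002      TRUE  FALSE           0.001 2026-09-24T02:49:10
```

The same experiments are reachable from a shell through the installed
`exec/trajspace` script (`run-example`, `inspect`, `find`, `merge`):

```
$ trajspace inspect multiply.h5 --depth 2
trajectory multiply
parameters <group>
  x <parameter:float, range[12]>
  y <parameter:float, range[12]>
results <group>
  runs <group>
config <group>
runs: 12 total, 12 completed, 0 failed
```

Predicate filtering finds runs without iterating them: over the bundled
cellular-automata exploration of rules `10, 30, 90, 110, 184, 190`,

```r
traj$find_run_indices("rule_number", function(r) r > 30 && r < 120)
#> [1] 2 3
```

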