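---
title: "trajspace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trajspace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajspace)
```

## The conceptual model

trajspace assumes the canonical layout of a numerical experiment:

1. **Pre-processing** — parameters are declared (name, default value,
   comment) and the exploration is chosen: an ordered set of points in the
   parameter space, expressed as equal-length value sequences, one entry per
   run. Typically only a small sub-space of the full parameter set is
   varied; the rest stays at its defaults.
2. **Run phase** — the model is executed once per point (a *single run*).
   Runs are independent by contract: nothing one run computes may influence
   another. This is what makes the phase embarrassingly parallel.
3. **Post-processing** (optional) — results are collected, summarised, and
   possibly the space is *expanded* with further points, alternating with
   the run phase (adaptive exploration).
4. **Analysis** (optional) — ideally a separate session that reloads the
   stored file and never touches the simulation code.

The ordered point set traces a trajectory through the space; the
`Trajectory` container carries that trajectory together with everything it
produced.

## Containers and type fidelity

Leaves of the tree are typed containers. A **parameter** holds one
dimension: a default value, an optional exploration range, and a lock.
Ranges are type-homogeneous — all elements of a range live in the same
dimension, so a range mixing integers and doubles is rejected
(`heterogeneous_range_error`). The supported kinds are scalars (logical,
integer, double, complex, character), 1-D vectors and 2-D matrices thereof,
and homogeneous non-nested lists; **results** additionally accept named
lists (mappings) and data frames. Each value carries a `type_tag`, and the
storage layer guarantees `decode(encode(v))` is identical to `v`, tag
included — an integer never silently becomes a double, a list never becomes
a vector. Custom kinds plug in through `register_container_kind(tag,
encode, decode)`; a file containing a custom tag can only be loaded by a
session whose registry knows that tag, which mirrors the general rule that
the loader needs access to container constructors at run time.

**Locking.** A parameter that has been used must not silently change
mid-experiment; such bugs are notoriously hard to track down. The open
design question is *when* "used" begins. Here: the first read through the
tree API **inside a run context** sets the lock. Plain introspection in an
interactive session (`traj$get("x")` outside any run) does not lock,
because making inspection destructive would punish exactly the exploratory
workflow the container is meant to support. Unlocking is explicit and emits
a warning. Value equality (used by merge deduplication) is bitwise —
explored points are user-specified literals, so no tolerance is applied.

## The tree and natural naming

Groups and leaves form a rooted tree (cycles are impossible by
construction); *links* may additionally alias existing nodes. Shortcut
resolution is breadth-first from the queried node: the match at minimal
depth wins, two distinct matches at the same minimal depth raise
`ambiguous_name_error` rather than guessing, and deeper matches shadowed by
a unique shallower one are ignored. Where a result and a parameter share a
leaf name, the same rule applies: the query must be lengthened, the
resolver never prefers one branch. Link chains are chased at most 8 hops
(`link_depth_error` beyond), which bounds pathological alias loops without
a cycle detector. Valid names are identifier-like (`[A-Za-z_][A-Za-z0-9_]*`)
and must avoid the reserved tokens `crun` and the `run_XXXXXXXX` pattern,
because names double as path components in attribute-style queries. `crun`
with no run selected (pointer −1) is a `not_found_error` naming the token.

Run indices are **0-based** throughout — run names (`run_00000000`), the
`index` column of the run table, `value_at()` and `find_run_indices()` all
agree — because the run name is an identifier shared with the on-disk
layout, not an R vector position. Predicate filtering evaluates in-memory
ranges only and never triggers disk loads.

`cartesian_product()` enumerates grids with the **first-listed parameter
cycling fastest**, so `list(x = 1:4, y = 6:8)` yields
`(1,6), (2,6), (3,6), (4,6), (1,7), ...` — the natural reading order of a
printed sweep.

## Storage layout and lazy loading

One trajectory maps one-to-one onto the group hierarchy of a single HDF5
file: every tree node is a group tagged with a `node_kind` attribute, leaf
payloads are datasets inside the leaf's group, and the run table lives
under `overview/` (no `node_kind`, hence invisible to the tree loader).
Scalars are stored as datasets rather than attributes so that all items are
uniformly addressable by lazy loads. Sequence fidelity (vector vs list,
tuple-like flattening) and text encoding are recorded in tags; data frames
are stored as one group with per-column datasets plus a column-order
attribute, avoiding dialect-specific table serialisers. Links are stored as
attribute-encoded aliases (a small group with a `target` attribute), which
the loader re-materialises; the HDF5 soft-link primitive is not exposed by
the binding used here and the alias encoding round-trips identically.
Group comments and annotations are stored as group attributes; annotation
order is not preserved (attributes are an unordered map).

Loading has three levels — `skeleton` (root metadata, run table, explored
ranges), `structure` (stubs for every node) and `full` — and the visible
node set grows monotonically across them. With `auto_load`, a resolution
miss first materialises the structure level, then loads the resolved
leaf's payload; for any query the lazy path returns exactly what a full
load would. The service counts item reads and writes, which is how the
tests observe "full load never touches disk" and "partial store touches
only its subtree".

Writes are single-writer: all storage goes through one process and handle,
even when runs execute in parallel (workers ship result leaves back to the
master). Storing is idempotent for unchanged nodes via dirty flags.
Deleting or replacing stored user data is unsupported
(`unsupported_operation_error`); the only sanctioned in-place changes are
bookkeeping (run table) and range growth through expansion, which is an
append, not a rewrite. Datasets over 1 KiB are chunked and zlib-compressed
(level 4); smaller items stay contiguous, since compressing tiny datasets
costs more space than it saves. A per-run bookkeeping write updates only
the completion flag of that run's row; runtimes and timestamps are flushed
once at the end of the batch — a crash therefore loses at most cosmetic
metadata, never completion state, which is what resume needs.

## The run environment

`run()` executes pending (not-yet-completed) runs in index order. Outcomes
are returned as a list of `(index, returned)` pairs sorted by index
regardless of completion order. A failing run is logged to both logs,
marked failed, and does **not** abort its siblings; after the batch the
first failure is re-raised wrapped with its run index. Partial results a
failed run added before its exception are kept and stored, and the record
is flagged, so post-mortem inspection sees exactly what the run produced.

With `multiproc = TRUE` the pending runs are dispatched in index order to a
fork pool (`parallel::mclapply`, `ncores` workers, prescheduled — no work
stealing, so dispatch is deterministic). Each worker receives a pruned
trajectory view: every parameter collapsed to its single value for that run
index, config entries, and no results — the minimal serialisation
consistent with run independence. Before the pool starts, the model and its
arguments are scanned for objects that cannot cross a process boundary
(connections, external pointers), raising `serialization_error` naming the
offending object. For deterministic models the outcome set and the stored
trees are identical to sequential execution, which the test suite asserts.

The framework never seeds global random number generators; models derive
seeds from their parameters (the automaton example carries an explicit
`seed` parameter). Progress reports state `completed/total` and an ETA
computed as the arithmetic mean runtime of completed runs times the number
remaining (no decay — runs are exchangeable by assumption). Reports are
emitted at most once per `report_interval` (default 10 s), or after every
run when single runs are slower than the interval. Each environment writes
two log files, `<name>_main.log` at the configured level and
`<name>_errors.log` at error severity only, so failures are findable
without scrolling a firehose.

## The example models

* **multiply** — `z = x * y` over the Cartesian grid
  `{1,2,3,4} x {6,7,8}`; 12 runs, outcomes `(0, 6.0) ... (11, 32.0)`.
  Exists to make every moving part visible at minimal size.
* **elementary cellular automata** — `n` binary cells updated for `k` steps
  by one of 256 three-cell transition rules, periodic boundaries; bit
  `4*s_left + 2*s_center + s_right` of the rule number gives the next
  state (rule 110's outputs, read back as binary, are its name). The
  experiment explores rules `10, 30, 90, 110, 184, 190` and stores the
  full `k x n` pattern per run. Defaults `ncells = 200`, `steps = 200`
  give patterns large enough to show structure while keeping the
  six-run experiment in the low seconds; the random initial row comes
  from the run's `seed` parameter, and an explicit `initial_state`
  override exists so oracle tests (e.g. the rule-90 XOR/Sierpinski
  recurrence) are deterministic.
* **greedy stochastic optimizer** — maximises
  `f(x) = -(x+4)^6 + 5(x-10)^4 - 2(x-4)^2 + x` by sampling, each
  generation, `popsize = 200` points from a normal of width
  `sigma = 0.5` centered at the best point so far, expanding the
  trajectory, running only the pending points, and keeping the maximum —
  30 generations by default, 6000 runs total. Automatic storing is off
  during the runs (each result is a single float; per-run storage would be
  pure overhead) and the tree is stored manually once at the end. The
  per-generation best is non-decreasing by construction.
* **LIF network** — `n` leaky integrate-and-fire neurons,
  `dV/dt = (I0 - V)/tau` plus instantaneous inhibitory kicks `w <= 0`
  delivered with probability-`p_conn` random coupling; threshold `VT`,
  reset to 0. Defaults (`n_neurons = 100`, `tau = 10` ms, `VT = 1`,
  `I0 = 1.1 VT`, `p_conn = 0.1`, `dt = 0.1` ms, `duration = 500` ms) are
  fixture conventions chosen to give regular supra-threshold firing, so
  the decoupled closed form `ISI = tau * ln(I0 / (I0 - VT))` is checkable
  against the forward-Euler integration within `2 dt`. Discretising the
  delta synapse requires an ordering choice: spikes detected at step `t`
  are delivered to targets at step `t + 1`, and there are no
  self-connections. Initial voltages are uniform in `[0, VT)` (an explicit
  `v_init` override exists for the closed-form test).

These models emulate the shapes of real exploration workloads — scalar
sweeps, per-run array results, adaptive expansion, stochastic dynamics —
but not their scale or heterogeneity: passing tests demonstrate the
correctness of the data management, not the scientific validity of any
particular simulation run through it.

## Numerical and design choices

* Floating-point comparisons on stored values and explored points are
  bitwise; tolerances appear only where a discretised simulation is checked
  against a continuous closed form (the LIF interspike interval, `2 dt`).
* Method names live on R6 objects (`traj$add_parameter(...)`), so user data
  names can never collide with API names; no prefix convention is needed
  on the data itself.
* The run phase boundary is enforced structurally: `add_parameter` raises
  `run_phase_error` once any run has started, while results may be added
  at any time.
* Reading a parameter during pre-processing does not lock it; only reads
  routed through a run context do (see Containers above).
* A derived-parameters branch is not implemented; the reserved top-level
  groups are exactly `parameters`, `results` and `config`.
* Problem sizes in the test suite (40–200 cells/steps for automata, a
  1000-run scalar sweep and 100 runs of 1000 x 125 arrays for the storage
  smoke test) are chosen as the smallest sizes that still exercise growth
  effects (run tables that must not be rewritten quadratically, datasets
  above and below the compression threshold).

## Known limitations

* One writer per file; no concurrent write sessions and no multi-host
  distribution of runs (the pool is fork-based, single machine).
* Stored data cannot be deleted or replaced in place; correcting a stored
  tree means storing to a fresh file.
* Sparse matrices and unit-aware quantities have no built-in containers;
  the custom-kind registry is the extension point.
* Merging takes the union of runs and per-run results only; non-run result
  leaves of the merged-in trajectory are not copied.
* `expand()` must re-name exactly the explored parameter set; partial
  un-exploration or re-dimensioning an executed trajectory is unsupported.
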