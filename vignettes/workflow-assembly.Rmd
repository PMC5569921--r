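---
title: "Assembling and running workflows with flowforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and running workflows with flowforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowforge)
```

## The problem

Genomics analyses are rarely one tool: they are chains and fan-outs of
aligners, callers, filters and summarizers, re-run constantly as methods
improve, as parameters are tuned, and as one caller is swapped for another.
Writing and maintaining that glue by hand — dependency bookkeeping, job
submission, logging, restartability, per-sample bookkeeping — is where most
of the engineering time goes, and it is exactly the part that contributes
nothing scientifically.

flowforge removes the glue. A workflow is a plain-text YAML configuration
over a library of reusable **components** (each a declaratively described
wrapper around one command-line tool). The configuration is compiled into a
validated directed acyclic graph (DAG) of tasks and executed by a run
manager that owns workspaces, scheduling, logging, resume, and
scatter–gather parallelization. No workflow code is ever written by the
user; changing an analysis means editing text and re-running `init`.

## The configuration model

A configuration has three groups of blocks:

* **system-specific** — `GENERAL` (paths, default resources) and
  `PIPELINE_INFO` (name, version, author). Updating only these lets the
  same workflow run on another machine.
* **user-specific** — `SHARED` (workflow-wide inputs and arguments) and
  `SAMPLES` (one parameter set per sample; the sweep axis). Re-running the
  same workflow on new inputs touches only these.
* **workflow-specific** — one `__TASK_i__` section per task, naming its
  component, its parameters, and per-task run options (resources,
  `use_cluster`, `parallel_run`, `breakpoint`, `boilerplate`,
  `output_dir_name`, `forced_dependencies`).

Data flow is declared by **IO-connections**: the value of a consuming
parameter is a `(task, parameter)` pair,

```yaml
__TASK_2__:
  component: comp_copy
  in_file: ('__TASK_1__', 'out_file')
```

which both feeds `__TASK_1__`'s `out_file` into `__TASK_2__` and orders the
two tasks. Both the quoted-tuple spelling above and a two-element YAML flow
list `[__TASK_1__, out_file]` are accepted and normalized internally; only
*exactly two-element* tuples are recognized, so one- or three-element
tuple-looking strings remain ordinary literals. A parameter may also hold a
*list* of connections (fan-in), an extension for merge-style consumers.

Several syntactic points were genuinely open and are fixed here by design:

* **SHARED/SAMPLES references.** Tasks cite workflow-wide values as
  `('__SHARED__', 'key')` and swept values as `('__SAMPLES__', 'key')`,
  mirroring the IO-connection syntax so the configuration has a single
  reference form.
* **Keywords.** Run-time values are interpolated with `$UPPER_SNAKE`
  tokens: `$RUN_ID`, `$SAMPLE_ID`, `$WORKFLOW_NAME`, `$TASK_NAME`. A
  literal dollar is written `$$`. Any other `$TOKEN` is an error rather
  than being silently kept — path typos should fail loudly at render time.
* **Unknown keys** inside a task's `run` block are warnings, not errors
  (forward compatibility); unknown *top-level* sections are errors.
* **YAML 1.1 pitfall.** Bare `y`/`n` scalars would normally parse as
  booleans, silently corrupting a sweep key named `n`. The parser keeps
  single-letter `y`/`n` literal while `true/yes/on` and `false/no/off`
  still resolve to logicals.

`validate_config()` returns an ordered diagnostics table
(`severity: location: message`) covering dangling references,
self-connections and self-dependencies, unknown components and parameters,
unfilled required placeholders, resource sanity, the parallelization
contract, ragged sweeps, and cycles. An empty error set is exactly the
compilability criterion. Two tasks declaring the same output path are
*warned about* rather than auto-serialized: an implicit edge would change
scheduling invisibly, and a forced dependency is the explicit remedy.

## Components

A component is a directory —
`component.yaml`, `wrapper`, `seed/` (the wrapped tool, in any language),
`README.md`, `tests/` — whose YAML definition declares the seed command
template, the parameters (with roles `input_file`, `output_file`,
`argument`, `flag`), resource defaults (memory `"1G"`, 1 CPU when
unstated), and an optional parallelization contract. The definition file
is the whole interface: the engine renders a shell command from it
(`--name value` pairs in declaration order, flags only when true, a
`{PARAMS}` placeholder for positional styles, `{COMPONENT_DIR}` for
seed-relative paths) and never interprets the seed itself. Rendering is a
pure function: equal definition, values and boilerplate give a byte-equal
command, which is what makes commands hashable and runs resumable. A
boilerplate fragment is joined with `&&` so a failing environment setup
aborts the task instead of running the tool in a broken environment.

## From configuration to execution plan

`build_graph()` maps task sections to nodes and IO-connections plus forced
dependencies to edges (kinds `io` and `forced`, distinguished for
reporting but identical for scheduling — a forced dependency is ordering
without data flow, e.g. waiting for an index file). Cycles are reported as
an explicit task-name path, found in DFS order; the first cycle suffices
for a config-time error, so no attempt is made to enumerate all of them.

`build_plan()` partitions the DAG into stages by longest-path depth
(Kahn-style): stage *k* holds the tasks whose deepest chain of
prerequisites has length *k*. Every edge crosses stages forward, so tasks
within one stage are pairwise independent and can run with maximal
concurrency. Within a stage, names are sorted lexicographically — a pure
tie-break that makes plans, logs and reports reproducible across runs and
platforms. The stage count is therefore one plus the longest path length,
which is what the test suite checks against a brute-force path-enumeration
oracle on random DAGs.

## Compiled artifacts

`init_workflow()` freezes a validated configuration into a directory
artifact: the exact config text, a manifest of component versions and
definition md5s, copies of the components, one concrete sub-workflow per
`SAMPLES` entry, and a launcher script. The artifact form was chosen over
generating standalone workflow source: the behavioral contract (a single
runnable entry point) is identical, but a frozen-data artifact is
inspectable and testable, and recompiling the same inputs is reproducible
by construction. Loading an artifact re-hashes the embedded component
definitions against the manifest and refuses on mismatch — if a component
drifted after compile time, the artifact no longer describes what would
run, and silently running the new code would defeat the provenance point.

## The run manager

Each invocation gets a run-ID-tagged tree,
`<out_root>/<run_id>/<sample>/{logs,outputs,scripts,sentinels}`, with
exactly those four subdirectories per sample. Run-IDs are UTC timestamps
plus a 4-character base-36 suffix; tests inject fixed IDs instead. Outputs
of a task land under `outputs/<output_dir_name or task name>/`, with
keywords interpolated, which is the whole results-directory customization
mechanism. Every task's fully rendered command is written to `scripts/` as
a small shell script (with `set -e -o pipefail` and its `mkdir -p`
preamble) — the run is auditable and any task reproducible by hand.

**Sentinels and resume.** On success a task writes a sentinel containing
an invocation hash. The hash covers the rendered command (with the run
root and artifact root replaced by placeholder tokens), the component
version, and — Merkle-style — the sorted hashes of its data-flow
predecessors. A task is skipped exactly when its sentinel matches. The
chained design is deliberate: hashing only the command and input *paths*
would leave a descendant's hash unchanged when an upstream parameter
changes (the paths stay the same), so "edit one task, rerun it and its
descendants" would silently under-run. Forced-dependency predecessors are
excluded from the chain because they carry no data. The token
normalization is equally deliberate: a paused run can be relocated to
another machine or directory (intermediates included) and resumed without
re-running anything, and recompiling an edited configuration into a fresh
artifact invalidates only what actually changed. Sentinels are written
atomically (write-then-rename), so a crash between tasks can only lose a
sentinel, never corrupt one — a re-run then repeats at most the
unrecorded task.

**Failure policy.** A failed task marks its dependents `blocked`;
independent branches continue, matching the DAG semantics. The stricter
stop-everything mode is available as `halt_on_first_failure`.

**Breakpoints.** A task with `breakpoint: true` pauses the run *after* it
completes (and with it everything scheduled at or before its stage): the
use cases — inspecting intermediate results, moving the remainder to a
machine that can reach a database — all require the pre-breakpoint work to
be finished. A breakpoint task that is *skipped* via its sentinel does not
re-pause, otherwise a paused run could never make progress on resume; the
third invocation of a finished run is a no-op.

**Scatter–gather.** A task whose component declares a parallelization
contract (`split_param` plus `merge_strategy`) and whose run options set
`parallel_run: true` is expanded at run time: one child per chunk, the
split parameter bound to the chunk, outputs redirected to chunk-suffixed
files, and a synthetic merge node that reassembles the serial result at
the original paths — so downstream consumers need no rewiring and the
graph stays acyclic. Chunks come from an `interval_source`: a BED file
(0-based, half-open — the BED convention is kept end to end) gives one
chunk per interval, an integer gives generic `i/n` shard tokens for
non-genomic tools. Merge strategies are `concat`, `concat_skip_header`
(first header kept), or a user command template with `{INPUTS}` and
`{OUTPUT}`. The merge node's hash chains over its children, so a changed
chunk invalidates the merge but an untouched re-run skips everything. The
contract that makes this meaningful — and that the tests assert — is
byte-identical equality between the merged and the serial output.

**Backends and concurrency.** The executor contract is a single blocking
call per rendered script; the engine owns ordering and bounded concurrency
(a forked worker pool of `num_jobs`, POSIX only). Three backends ship:
`local_backend()` (bash), `shell_backend(template)` — a generic batch
submission template with `{SCRIPT}`/`{LOG}`/`{MEMORY}`/`{NUM_CPUS}`
placeholders rather than scheduler-specific code, used for tasks with
`use_cluster: true` — and `noop_backend()`, a dry-run that schedules,
sentinels and reports without executing, useful both for previewing a
workflow and for exercising the engine's ordering guarantees cheaply.
Sweep sub-workflows run concurrently across samples when `num_jobs`
allows. Per-sample JSON reports plus a run-level index are written into
the workspace; a combined cross-sample report is intentionally not
synthesized beyond the index.

## What the fixture suite emulates — and what it does not

`generate_fixture_suite()` writes seven shell-seeded toy components
(text generation, copying, line counting, per-interval variant counting
with and without headers, header-aware table merging, fail-on-demand) and
seedable toy data: FASTA-like text, a sorted non-overlapping BED, a
variant position table, small headered tables. The interval counter is
shaped like a scatter/gather variant-calling step — its serial output
equals the concatenation of its per-interval outputs, which is precisely
what makes the serial-versus-parallel equality a meaningful check rather
than a tautology.

The suite emulates the *control-flow* properties of real pipelines:
dependency shapes, chunkable interval work, header-merging, failures,
multi-sample sweeps. It does not emulate their *data* properties — tool
runtimes are milliseconds, outputs are tiny and deterministic, and no real
aligner or caller semantics are involved. Green tests therefore establish
that the engine schedules, resumes, merges and isolates correctly; they
say nothing about any particular bioinformatic tool, which is by design:
the engine never interprets tool output.

Checks run at deliberately small problem sizes — workflows of up to 8
tasks, 10-interval BEDs, 200 random DAGs against the brute-force depth
oracle, 50 randomized concurrency runs for the no-overlap property —
chosen so the full suite exercises every feature in about a minute while
the randomized repetitions still give the properties real bite.

## Known limitations

* Resuming on another machine requires the intermediate files to be
  present; the engine stages no data between machines.
* Components are executed in the caller's environment: tool installation
  and dependency management remain the user's responsibility (boilerplates
  help, containerization is out of scope).
* The cluster backend is a generic blocking-submit template; schedulers
  whose submission is asynchronous need a wrapping script that waits.
* Concurrency uses forked workers, so parallel execution is POSIX-only
  (serial execution works anywhere R and bash do).
* Configuration dialects other than YAML, config inheritance/includes, and
  a versioned component registry are non-goals.
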