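# flowforge

Assemble and run command-line workflows from a plain-text configuration —
no workflow code.

Bioinformatics analyses are DAGs of command-line tools (align, call,
filter, summarize) that are re-wired constantly: a new caller, a swept
parameter, a subset re-run. flowforge is for the developers of such
pipelines. Each tool is wrapped once as a **component** — a directory with
a declarative `component.yaml` describing its parameters, resources and
(optionally) how it splits over genomic intervals and merges again. A
**workflow** is then nothing but a YAML file instantiating components as
tasks and wiring them with IO-connections:

```yaml
__TASK_1__:
  out_file: 'foo.txt'
__TASK_2__:
  in_file: ('__TASK_1__', 'out_file')   # TASK_2 consumes TASK_1's output
```

The engine compiles that text into a validated DAG, partitions it into
maximally concurrent stages by longest-path depth, and runs it with
run-ID-tagged workspaces, per-task scripts and logs, sentinel-based
resume (skip exactly what is unchanged, rerun a changed task *and its
data-flow descendants*), breakpoints for controlled pause/resume, forced
dependencies (ordering without data flow), scatter–gather over BED
intervals with automatic merge, `$RUN_ID`/`$SAMPLE_ID`-style keyword
interpolation, and parameter sweeping over a `SAMPLES` block.

## Worked example

A two-task workflow on the built-in toy fixtures: count variants per BED
interval — scattered over the 10 intervals and merged — then count the
result's lines.

```r
library(flowforge)
fx <- generate_fixture_suite("fixtures", seed = 1)

cfg <- "
PIPELINE_INFO: {name: toy_counts}
SHARED:
  variants: fixtures/data/variants.tsv
  targets: fixtures/data/targets.bed
__TASK_1__:
  component: comp_interval_count
  run: {parallel_run: true, interval_source: fixtures/data/targets.bed}
  variants: ('__SHARED__', 'variants')
  intervals: ('__SHARED__', 'targets')
  out_file: counts.tsv
__TASK_2__:
  component: comp_linecount
  in_file: ('__TASK_1__', 'out_file')
  out_file: n_regions.txt
"
wf <- init_workflow(cfg, fx$registry, out_dir = ".", name = "toy_counts")
wf
#> <compiled_workflow> toy_counts at /tmp/readme_demo/toy_counts
#>   2 task(s), 1 sub-workflow(s), components: comp_interval_count, comp_linecount

report <- execute_workflow(wf, num_jobs = 2, run_id = "20260926-0001")
report
#> <run_report> toy_counts  run-ID 20260926-0001  status: completed
#>   done=12
```

Twelve tasks ran, not two: the interval counter was scattered into ten
chunk children (one per BED interval, stage 1) plus a merge task, and the
line counter followed:

```r
head(report$tasks[, c("task", "status", "stage")], 4)
#>              task status stage
#> 1 __TASK_1__.c001   done     1
#> 2 __TASK_1__.c002   done     1
#> 3 __TASK_1__.c003   done     1
#> 4 __TASK_1__.c004   done     1

readLines(file.path(report$root, "run", "outputs", "__TASK_1__", "counts.tsv"))[1:3]
#> [1] "chr1\t965\t2482\t13"  "chr1\t2812\t3805\t11" "chr1\t4748\t4771\t0"
```

Each line is `chrom start end count`: 13 toy variants fall in
`chr1:965-2482`, and so on; the merged file is byte-identical to what an
unsplit run produces. Everything about the run lives under
`toy_counts/runs/20260926-0001/run/` in the four standard subdirectories
`logs/`, `outputs/`, `scripts/`, `sentinels/`. Calling
`execute_workflow(wf, resume = "20260926-0001")` again reports every task
as `skipped`.

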