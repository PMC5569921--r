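# shared fixtures: every test builds its inputs in code, nothing is stored

local_fixture_suite <- function(seed = 7L, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_fixture_suite(dir, seed = seed)
}

# two-task chain in the configuration language: text generator -> copier
chain_config <- function(n = 5L, out1 = "a.txt", out2 = "b.txt") {
  sprintf("
PIPELINE_INFO: {name: chain}
__TASK_1__:
  component: comp_textgen
  n: %d
  out_file: %s
__TASK_2__:
  component: comp_copy
  in_file: ('__TASK_1__', 'out_file')
  out_file: %s
", n, out1, out2)
}

# three-task chain A -> B -> C plus an independent task D
chain_plus_branch_config <- function(n = 5L) {
  sprintf("
PIPELINE_INFO: {name: chainbr}
__TASK_A__: {component: comp_textgen, n: %d, out_file: a.txt}
__TASK_B__:
  component: comp_copy
  in_file: ('__TASK_A__', 'out_file')
  out_file: b.txt
__TASK_C__:
  component: comp_linecount
  in_file: ('__TASK_B__', 'out_file')
  out_file: c.txt
__TASK_D__: {component: comp_textgen, n: 2, tag: other, out_file: d.txt}
", n)
}

# interval-counting workflow, serial or scattered over the BED
interval_config <- function(variants, bed, parallel = FALSE,
                            component = "comp_interval_count") {
  run_line <- if (parallel) {
    sprintf("  run: {parallel_run: true, interval_source: '%s'}\n", bed)
  } else ""
  sprintf("
PIPELINE_INFO: {name: intervals}
SHARED: {variants: '%s', bed: '%s'}
__TASK_1__:
  component: %s
%s  variants: ('__SHARED__', 'variants')
  intervals: ('__SHARED__', 'bed')
  out_file: counts.tsv
", variants, bed, component, run_line)
}

compile_fixture_workflow <- function(fx, config_text, name = "wf",
                                     env = parent.frame()) {
  out <- withr::local_tempdir(.local_envir = env)
  init_workflow(config_text, fx$registry, out_dir = out, name = name)
}

read_output <- function(report, sample, task, file) {
  readLines(file.path(report$root, sample, "outputs", task, file))
}

## ---- independent scheduling oracle -----------------------------------------

# brute-force longest-path depth: enumerate every simple path ending at each
# node and take the maximum length; independent of the engine's Kahn pass
oracle_depths <- function(nodes, edges) {
  preds <- function(v) unique(edges$from[edges$to == v])
  longest_to <- function(v, seen = character()) {
    p <- setdiff(preds(v), seen)
    if (!length(p)) return(0L)
    max(vapply(p, function(u) 1L + longest_to(u, c(seen, v)), integer(1)))
  }
  stats::setNames(vapply(nodes, longest_to, integer(1)), nodes)
}

# random DAG over n nodes: edges only from earlier to later in a fixed
# labelling, so acyclicity holds by construction
random_dag <- function(n, p = 0.35) {
  nodes <- sprintf("__T%d__", seq_len(n))
  from <- character(); to <- character()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (stats::runif(1) < p) { from <- c(from, nodes[i]); to <- c(to, nodes[j]) }
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to,
                          kind = rep("forced", length(from)),
                          stringsAsFactors = FALSE))
}

# render a random DAG as a runnable configuration: every node is a text
# generator, edges become forced dependencies (ordering without data flow)
dag_config <- function(dag, delay = NULL) {
  sections <- vapply(dag$nodes, function(v) {
    fds <- dag$edges$from[dag$edges$to == v]
    fd_line <- if (length(fds)) {
      sprintf("  forced_dependencies: [%s]\n", paste(fds, collapse = ", "))
    } else ""
    delay_line <- if (!is.null(delay)) sprintf("  delay: %s\n", delay) else ""
    sprintf("%s:\n  component: comp_textgen\n  n: 1\n%s%s  out_file: %s.txt\n",
            v, fd_line, delay_line, gsub("_", "", v))
  }, character(1))
  paste0("PIPELINE_INFO: {name: dagfix}\n", paste(sections, collapse = ""))
}

# run a DAG config end to end and return the per-task report rows
run_dag_config <- function(fx, cfg, num_jobs = 2L, backend = noop_backend(),
                           env = parent.frame()) {
  wf <- compile_fixture_workflow(fx, cfg, name = "dagwf", env = env)
  execute_workflow(wf, backend = backend, num_jobs = num_jobs, run_id = "R1")
}

expect_edges_respected <- function(report, edges) {
  tasks <- report$tasks
  for (k in seq_len(nrow(edges))) {
    u <- tasks[tasks$task == edges$from[k], ]
    v <- tasks[tasks$task == edges$to[k], ]
    expect_true(u$finished <= v$started,
                label = sprintf("finish(%s) <= start(%s)", edges$from[k], edges$to[k]))
  }
}
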