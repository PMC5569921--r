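# run manager: workspaces, sentinel-based resume, breakpoints, failure
# policy, scatter-gather parallelization with merge

test_that("workspaces have exactly the four standard subdirectories per sample", {
  out <- withr::local_tempdir()
  st <- create_run_workspace(out, "R1", c("SA1", "SA2"))
  expect_named(st$workspaces, c("SA1", "SA2"))
  for (sid in c("SA1", "SA2")) {
    subdirs <- sort(basename(list.dirs(file.path(out, "R1", sid), recursive = FALSE)))
    expect_equal(subdirs, c("logs", "outputs", "scripts", "sentinels"))
  }
  # no samples: one default workspace
  st0 <- create_run_workspace(out, "R2")
  expect_named(st0$workspaces, "run")
  # idempotent re-creation clobbers nothing
  marker <- file.path(out, "R1", "SA1", "outputs", "keep.txt")
  writeLines("x", marker)
  before <- sort(list.files(file.path(out, "R1"), recursive = TRUE))
  create_run_workspace(out, "R1", c("SA1", "SA2"))
  expect_equal(sort(list.files(file.path(out, "R1"), recursive = TRUE)), before)
  expect_equal(readLines(marker), "x")
})

test_that("a fresh chain run executes in order and leaves sentinels; rerun skips all", {
  fx <- local_fixture_suite()
  wf <- compile_fixture_workflow(fx, chain_config(n = 7))
  r1 <- execute_workflow(wf, run_id = "R1")
  expect_equal(r1$status, "completed")
  expect_equal(r1$tasks$status, c("done", "done"))
  expect_true(r1$tasks$finished[1] <= r1$tasks$started[2])
  expect_equal(read_output(r1, "run", "__TASK_2__", "b.txt"),
               sprintf("line %d tag fixture", 1:7))
  sentinels <- list.files(file.path(r1$root, "run", "sentinels"), pattern = "\\.ok$")
  expect_setequal(sentinels, c("__TASK_1__.ok", "__TASK_2__.ok"))
  # resume idempotence: zero submissions the second time
  r2 <- execute_workflow(wf, resume = "R1")
  expect_equal(r2$tasks$status, c("skipped", "skipped"))
  expect_true(all(is.na(r2$tasks$exit_code)))
  # a fresh-run collision with an existing run directory is refused
  expect_error(execute_workflow(wf, run_id = "R1"), "resume",
               class = "flowforge_validation_error")
  expect_error(execute_workflow(wf, resume = "NOPE"), "NOPE",
               class = "flowforge_validation_error")
})

test_that("editing a task parameter reruns exactly that task and its descendants", {
  fx <- local_fixture_suite()
  out_root <- withr::local_tempdir()
  wf1 <- compile_fixture_workflow(fx, chain_plus_branch_config(n = 5), name = "v1")
  r1 <- execute_workflow(wf1, out_root = out_root, run_id = "R1")
  expect_equal(r1$status, "completed")
  # same workflow with one upstream parameter changed
  wf2 <- compile_fixture_workflow(fx, chain_plus_branch_config(n = 6), name = "v2")
  r2 <- execute_workflow(wf2, out_root = out_root, resume = "R1")
  rerun <- r2$tasks$task[r2$tasks$status == "done"]
  # oracle: the changed task plus its reachability set in the DAG
  g <- build_graph(wf1$sub_workflows$run, fx$registry)
  expect_setequal(rerun, c("__TASK_A__", descendants(g, "__TASK_A__")))
  expect_equal(r2$tasks$status[r2$tasks$task == "__TASK_D__"], "skipped")
  expect_equal(read_output(r2, "run", "__TASK_C__", "c.txt"), "6")
})

test_that("a deleted sentinel reruns only its task; sentineled tasks never rerun", {
  fx <- local_fixture_suite()
  wf <- compile_fixture_workflow(fx, chain_plus_branch_config())
  r1 <- execute_workflow(wf, run_id = "R1")
  # crash emulation: the engine stopped after __TASK_B__ ran but before its
  # sentinel was recorded
  unlink(file.path(r1$root, "run", "sentinels", "__TASK_B__.ok"))
  r2 <- execute_workflow(wf, resume = "R1")
  expect_equal(sort(r2$tasks$task[r2$tasks$status == "done"]), "__TASK_B__")
  expect_equal(sum(r2$tasks$status == "skipped"), 3L)
})

test_that("breakpoints pause after the marked task and resume runs the remainder", {
  fx <- local_fixture_suite()
  cfg <- "
__TASK_A__: {component: comp_textgen, n: 2, out_file: a.txt}
__TASK_B__:
  component: comp_copy
  run: {breakpoint: true}
  in_file: ('__TASK_A__', 'out_file')
  out_file: b.txt
__TASK_C__:
  component: comp_linecount
  in_file: ('__TASK_B__', 'out_file')
  out_file: c.txt
"
  wf <- compile_fixture_workflow(fx, cfg)
  r1 <- execute_workflow(wf, run_id = "R1")
  expect_equal(r1$status, "paused")
  expect_equal(r1$tasks$status, c("done", "done", "not_started"))
  r2 <- execute_workflow(wf, resume = "R1")
  expect_equal(r2$status, "completed")
  expect_equal(r2$tasks$status, c("skipped", "skipped", "done"))
  r3 <- execute_workflow(wf, resume = "R1")
  expect_equal(r3$tasks$status, rep("skipped", 3))
})

test_that("a breakpoint on the terminal task completes everything then pauses", {
  fx <- local_fixture_suite()
  wf <- compile_fixture_workflow(fx, chain_config())
  wf <- apply_breakpoint(wf, "__TASK_2__")
  r1 <- execute_workflow(wf, run_id = "R1")
  expect_equal(r1$status, "paused")
  expect_equal(r1$tasks$status, c("done", "done"))
  r2 <- execute_workflow(wf, resume = "R1")
  expect_equal(r2$status, "completed")
  expect_equal(sum(r2$tasks$status == "done"), 0L)
  expect_error(apply_breakpoint(wf, "__TASK_9__"), "__TASK_9__",
               class = "flowforge_validation_error")
})

test_that("a mid-branch breakpoint holds back later stages of other branches", {
  fx <- local_fixture_suite()
  # branch 1: A -> B(breakpoint) -> C ; branch 2: X -> Y; Y sits at a later
  # stage than the breakpoint and must not start in run 1
  cfg <- "
__TASK_A__: {component: comp_textgen, n: 1, out_file: a.txt}
__TASK_B__:
  component: comp_copy
  run: {breakpoint: true}
  in_file: ('__TASK_A__', 'out_file')
  out_file: b.txt
__TASK_C__:
  component: comp_linecount
  in_file: ('__TASK_B__', 'out_file')
  out_file: c.txt
__TASK_X__: {component: comp_textgen, n: 1, tag: x, out_file: x.txt}
__TASK_Y__:
  component: comp_copy
  in_file: ('__TASK_X__', 'out_file')
  out_file: y.txt
"
  wf <- compile_fixture_workflow(fx, cfg)
  r1 <- execute_workflow(wf, run_id = "R1")
  st <- stats::setNames(r1$tasks$status, r1$tasks$task)
  expect_equal(unname(st[c("__TASK_A__", "__TASK_B__", "__TASK_X__", "__TASK_Y__")]),
               c("done", "done", "done", "done"))
  expect_equal(unname(st["__TASK_C__"]), "not_started")
  # oracle: stage arithmetic — everything at a stage <= stage(B) ran
  plan <- build_plan(build_graph(wf$sub_workflows$run, fx$registry))
  bp_stage <- stage_of_task(plan, "__TASK_B__")
  for (tn in r1$tasks$task) {
    if (stage_of_task(plan, tn) <= bp_stage) {
      expect_equal(unname(st[tn]), "done")
    } else expect_equal(unname(st[tn]), "not_started")
  }
})

test_that("scattered execution merges to the byte-identical serial result", {
  fx <- local_fixture_suite()
  bed2 <- file.path(withr::local_tempdir(), "two.bed")
  withr::with_seed(5, write_toy_bed(bed2, n = 2))
  serial <- execute_workflow(
    compile_fixture_workflow(fx, interval_config(fx$data$variants, bed2), "s"),
    run_id = "R1")
  par <- execute_workflow(
    compile_fixture_workflow(fx, interval_config(fx$data$variants, bed2,
                                                 parallel = TRUE), "p"),
    run_id = "R1", num_jobs = 2)
  expect_equal(serial$status, "completed")
  expect_equal(par$status, "completed")
  # 2 children + 1 merge
  expect_setequal(par$tasks$task,
                  c("__TASK_1__.c001", "__TASK_1__.c002", "__TASK_1__.merge"))
  expect_identical(read_output(par, "run", "__TASK_1__", "counts.tsv"),
                   read_output(serial, "run", "__TASK_1__", "counts.tsv"))
})

test_that("a single chunk still gathers through a merge and equals serial", {
  fx <- local_fixture_suite()
  bed1 <- file.path(withr::local_tempdir(), "one.bed")
  withr::with_seed(5, write_toy_bed(bed1, n = 1, chroms = "chr1"))
  serial <- execute_workflow(
    compile_fixture_workflow(fx, interval_config(fx$data$variants, bed1), "s"),
    run_id = "R1")
  par <- execute_workflow(
    compile_fixture_workflow(fx, interval_config(fx$data$variants, bed1,
                                                 parallel = TRUE), "p"),
    run_id = "R1")
  expect_setequal(par$tasks$task, c("__TASK_1__.c001", "__TASK_1__.merge"))
  expect_identical(read_output(par, "run", "__TASK_1__", "counts.tsv"),
                   read_output(serial, "run", "__TASK_1__", "counts.tsv"))
})

test_that("concat_skip_header merge keeps a single header across chunks", {
  fx <- local_fixture_suite()
  bed3 <- file.path(withr::local_tempdir(), "three.bed")
  withr::with_seed(9, write_toy_bed(bed3, n = 3, chroms = "chr1"))
  par <- execute_workflow(
    compile_fixture_workflow(
      fx, interval_config(fx$data$variants, bed3, parallel = TRUE,
                          component = "comp_region_table"), "p"),
    run_id = "R1", num_jobs = 2)
  expect_equal(par$status, "completed")
  got <- read_output(par, "run", "__TASK_1__", "counts.tsv")
  # hand-built expectation: header plus one counted row per interval
  bed <- utils::read.table(bed3, col.names = c("chrom", "start", "end"))
  vars <- utils::read.table(fx$data$variants, col.names = c("chrom", "pos"))
  counts <- mapply(function(ch, s, e) sum(vars$chrom == ch & vars$pos >= s & vars$pos < e),
                   bed$chrom, bed$start, bed$end)
  expected <- c("chrom\tstart\tend\tcount",
                sprintf("%s\t%d\t%d\t%d", bed$chrom, bed$start, bed$end, counts))
  expect_identical(got, expected)
  expect_equal(sum(grepl("^chrom\t", got)), 1L)
})

test_that("a failed task blocks its dependents while independent branches finish", {
  fx <- local_fixture_suite()
  tmp <- withr::local_tempdir()
  trigger <- file.path(tmp, "trigger")
  file.create(trigger)
  cfg <- sprintf("
__TASK_F__: {component: comp_fail_on_demand, trigger: '%s', out_file: f.txt}
__TASK_G__:
  component: comp_copy
  in_file: ('__TASK_F__', 'out_file')
  out_file: g.txt
__TASK_H__: {component: comp_textgen, n: 1, out_file: h.txt}
", trigger)
  wf <- compile_fixture_workflow(fx, cfg)
  r1 <- execute_workflow(wf, run_id = "R1")
  st <- stats::setNames(r1$tasks$status, r1$tasks$task)
  expect_equal(r1$status, "failed")
  expect_equal(unname(st[c("__TASK_F__", "__TASK_G__", "__TASK_H__")]),
               c("failed", "blocked", "done"))
  # clear the fault and resume: only the failed task and its dependent run
  unlink(trigger)
  r2 <- execute_workflow(wf, resume = "R1")
  st2 <- stats::setNames(r2$tasks$status, r2$tasks$task)
  expect_equal(r2$status, "completed")
  expect_equal(unname(st2[c("__TASK_F__", "__TASK_G__", "__TASK_H__")]),
               c("done", "done", "skipped"))
})

test_that("forced dependencies serialize tasks that share no data", {
  fx <- local_fixture_suite()
  cfg <- "
__TASK_1__: {component: comp_textgen, n: 1, delay: 0.05, out_file: a.txt}
__TASK_2__:
  component: comp_textgen
  n: 1
  tag: second
  delay: 0.05
  out_file: b.txt
  forced_dependencies: [__TASK_1__]
"
  wf <- compile_fixture_workflow(fx, cfg)
  for (i in 1:3) {
    r <- execute_workflow(wf, run_id = sprintf("R%d", i), num_jobs = 2)
    expect_equal(r$status, "completed")
    expect_true(r$tasks$finished[r$tasks$task == "__TASK_1__"] <=
                r$tasks$started[r$tasks$task == "__TASK_2__"])
  }
})

test_that("keywords, custom output directories and boilerplates shape the workspace", {
  fx <- local_fixture_suite()
  cfg <- "
PIPELINE_INFO: {name: tour}
SAMPLES:
  SA1: {n: 2}
  SA2: {n: 4}
__TASK_1__:
  component: comp_textgen
  run: {boilerplate: 'echo boilerplate-ran'}
  n: ('__SAMPLES__', 'n')
  output_dir_name: results_$SAMPLE_ID
  out_file: $RUN_ID.txt
"
  wf <- compile_fixture_workflow(fx, cfg)
  r <- execute_workflow(wf, run_id = "RX", num_jobs = 2)
  expect_equal(r$status, "completed")
  for (sid in c("SA1", "SA2")) {
    f <- file.path(r$root, sid, "outputs", paste0("results_", sid), "RX.txt")
    expect_true(file.exists(f))
    log <- readLines(file.path(r$root, sid, "logs", "__TASK_1__.log"))
    expect_true(any(grepl("boilerplate-ran", log)))
  }
  expect_length(readLines(file.path(r$root, "SA2", "outputs", "results_SA2", "RX.txt")), 4L)
})

test_that("the workspace can be relocated between pause and resume", {
  fx <- local_fixture_suite()
  root_a <- file.path(withr::local_tempdir(), "runs_a")
  root_b <- file.path(withr::local_tempdir(), "runs_b")
  wf <- apply_breakpoint(compile_fixture_workflow(fx, chain_config()), "__TASK_1__")
  r1 <- execute_workflow(wf, out_root = root_a, run_id = "R1")
  expect_equal(r1$status, "paused")
  file.rename(root_a, root_b)
  r2 <- execute_workflow(wf, out_root = root_b, resume = "R1")
  expect_equal(r2$status, "completed")
  expect_equal(stats::setNames(r2$tasks$status, r2$tasks$task),
               c("__TASK_1__" = "skipped", "__TASK_2__" = "done"))
})

test_that("the dry-run backend schedules everything without executing anything", {
  fx <- local_fixture_suite()
  wf <- compile_fixture_workflow(fx, chain_config())
  r <- execute_workflow(wf, backend = noop_backend(), run_id = "R1")
  expect_equal(r$status, "completed")
  expect_equal(r$tasks$status, c("done", "done"))
  expect_false(file.exists(file.path(r$root, "run", "outputs", "__TASK_1__", "a.txt")))
  # scripts were still rendered for inspection
  expect_true(file.exists(file.path(r$root, "run", "scripts", "__TASK_1__.sh")))
})

test_that("the shell backend template reproduces the local result", {
  fx <- local_fixture_suite()
  cfg <- "
__TASK_1__:
  component: comp_textgen
  run: {use_cluster: true}
  n: 3
  out_file: a.txt
"
  wf <- compile_fixture_workflow(fx, cfg)
  r <- execute_workflow(wf, backend = shell_backend("bash {SCRIPT} > {LOG} 2>&1"),
                        run_id = "R1")
  expect_equal(r$status, "completed")
  expect_equal(read_output(r, "run", "__TASK_1__", "a.txt"),
               sprintf("line %d tag fixture", 1:3))
})
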