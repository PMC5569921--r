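# Run manager: executes a compiled workflow. Every invocation gets a
# run-ID-tagged workspace tree
#   <out_root>/<run_id>/<sample>/{logs,outputs,scripts,sentinels}
# Tasks run stage by stage with bounded concurrency; each successful task
# leaves a sentinel recording a content hash of its invocation, so a later
# invocation skips unchanged tasks and reruns exactly what changed (and its
# data-flow descendants). Breakpoints pause a run after a marked task;
# parallelizable tasks are scattered over interval chunks and gathered by a
# synthetic merge task.

WORKSPACE_SUBDIRS <- c("logs", "outputs", "scripts", "sentinels")
WSROOT_TOKEN <- "__WSROOT__"

#' Generate a fresh run identifier
#'
#' UTC timestamp plus a 4-character base-36 suffix, e.g.
#' `20250101-120000-a3fz`. Unique per invocation for all practical purposes;
#' tests inject fixed run-IDs through the `run_id` argument of
#' [execute_workflow()] instead.
#'
#' @param time a `POSIXct`; defaults to now.
#' @return a run-ID string.
#' @export
new_run_id <- function(time = Sys.time()) {
  suffix <- paste(sample(c(letters, 0:9), 4, replace = TRUE), collapse = "")
  paste0(format(time, "%Y%m%d-%H%M%S", tz = "UTC"), "-", suffix)
}

new_workspace <- function(sample_root) {
  dirs <- as.list(file.path(sample_root, WORKSPACE_SUBDIRS))
  names(dirs) <- paste0(WORKSPACE_SUBDIRS, "_dir")
  structure(c(list(root = sample_root), dirs), class = "workspace")
}

#' Create the run-ID-tagged workspace tree
#'
#' Makes `<out_root>/<run_id>/<sample>/` for every sample, each with exactly
#' the four standard subdirectories: `logs` (log files), `outputs` (all
#' files the components produce), `scripts` (the generated per-task shell
#' scripts) and `sentinels` (completion markers driving resume). With no
#' samples, a single workspace named `"run"` is made. The operation is
#' idempotent: re-creating an existing run's tree touches nothing.
#'
#' @param out_root writable directory under which run trees live.
#' @param run_id run identifier tagging this tree.
#' @param sample_ids character vector of sample ids (may be empty).
#' @return a `run_state`: list with `run_id`, `root` and `workspaces`
#'   (named list of per-sample `workspace` objects).
#' @export
create_run_workspace <- function(out_root, run_id, sample_ids = character()) {
  stopifnot(is_string(out_root), is_string(run_id))
  if (!length(sample_ids)) sample_ids <- "run"
  root <- file.path(out_root, run_id)
  workspaces <- lapply(sample_ids, function(sid) {
    ws <- new_workspace(file.path(root, sid))
    for (d in ws[paste0(WORKSPACE_SUBDIRS, "_dir")]) {
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    }
    ws
  })
  names(workspaces) <- sample_ids
  structure(list(run_id = run_id, root = root, workspaces = workspaces),
            class = "run_state")
}

## ---- chunks and scatter/gather ---------------------------------------------

#' Chunk specification for scatter–gather parallelization
#'
#' @param chunk_id identifier unique within the task (e.g. `"c001"`).
#' @param value the value bound to the component's `split_param` for this
#'   chunk: a per-chunk interval (BED) file path, or a generic shard token.
#' @param region optional 3-element list (`chrom`, `start`, `end`), 0-based
#'   half-open, when the chunk derives from a genomic interval.
#' @return an object of class `chunk_spec`.
#' @export
chunk_spec <- function(chunk_id, value, region = NULL) {
  stopifnot(is_string(chunk_id))
  structure(list(chunk_id = chunk_id, value = value, region = region),
            class = "chunk_spec")
}

# read a 3+ column BED file (0-based, half-open); validates coordinates
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("interval file '%s' does not exist", path))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop(sprintf("interval file '%s' has fewer than 3 columns", path))
  bed <- bed[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  if (!is.numeric(bed$start) || !is.numeric(bed$end) || any(bed$start < 0) ||
      any(bed$end <= bed$start)) {
    stop(sprintf("interval file '%s' is not valid 0-based half-open BED", path))
  }
  bed
}

# chunks for a task: an integer interval_source gives generic shard tokens
# "i/n"; a BED path gives one chunk per interval, each written out as a
# single-line BED file under the workspace scripts directory
derive_chunks <- function(interval_source, task_name, ws) {
  n_shards <- suppressWarnings(as.integer(interval_source))
  if (!is.na(n_shards) && !grepl("[^0-9]", as.character(interval_source))) {
    if (n_shards < 1L) stop("shard count must be >= 1")
    return(lapply(seq_len(n_shards), function(i) {
      chunk_spec(sprintf("c%03d", i), sprintf("%d/%d", i, n_shards))
    }))
  }
  bed <- read_bed(interval_source)
  chunk_dir <- file.path(ws$scripts_dir, "chunks", task_name)
  dir.create(chunk_dir, recursive = TRUE, showWarnings = FALSE)
  lapply(seq_len(nrow(bed)), function(i) {
    id <- sprintf("c%03d", i)
    f <- file.path(chunk_dir, paste0(id, ".bed"))
    utils::write.table(bed[i, ], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    chunk_spec(id, f, region = as.list(bed[i, ]))
  })
}

chunk_node_name <- function(task, chunk_id) paste0(task, ".", chunk_id)
merge_node_name <- function(task) paste0(task, ".merge")

#' Expand a parallelizable task into chunk children plus a merge task
#'
#' Scatter–gather: the task node is replaced by one child per chunk — with
#' the component's `split_param` bound to the chunk and every output
#' redirected to a chunk-suffixed file — and a synthetic merge node that
#' depends on all children and applies the component's `merge_strategy` to
#' reassemble the outputs the serial run would have produced. Incoming
#' edges are copied to every child; downstream consumers hang off the merge
#' node, whose outputs land at the original task's paths. The graph stays
#' acyclic.
#'
#' @param graph a `workflow_graph`.
#' @param task_name the node to expand; its component must declare a
#'   parallelization contract.
#' @param chunks non-empty list of [chunk_spec()] objects with unique ids.
#' @return the expanded `workflow_graph`.
#' @export
parallelize_task <- function(graph, task_name, chunks) {
  stopifnot(inherits(graph, "workflow_graph"), task_name %in% graph$nodes,
            length(chunks) >= 1L)
  ids <- vapply(chunks, `[[`, "", "chunk_id")
  if (anyDuplicated(ids)) stop("chunk ids must be unique within a task")
  payload <- graph$payload[[task_name]]
  comp <- payload$component
  if (is.null(comp$parallelization)) {
    abort_validation(sprintf(
      "task %s: component '%s' declares no parallelization contract",
      task_name, comp$name))
  }
  child_names <- vapply(chunks, function(ch) chunk_node_name(task_name, ch$chunk_id), "")
  mname <- merge_node_name(task_name)
  e <- graph$edges
  incoming <- e[e$to == task_name, , drop = FALSE]
  outgoing <- e[e$from == task_name, , drop = FALSE]
  rest <- e[e$to != task_name & e$from != task_name, , drop = FALSE]
  new_edges <- rbind(
    rest,
    if (nrow(incoming)) do.call(rbind, lapply(child_names, function(cn) {
      transform(incoming, to = cn)
    })),
    data.frame(from = child_names, to = mname, kind = "io", stringsAsFactors = FALSE),
    if (nrow(outgoing)) transform(outgoing, from = mname)
  )
  nodes <- c(setdiff(graph$nodes, task_name), child_names, mname)
  payloads <- graph$payload
  payloads[[task_name]] <- NULL
  for (i in seq_along(chunks)) {
    payloads[[child_names[i]]] <- list(task = payload$task, component = comp,
                                       kind = "chunk", parent = task_name,
                                       chunk = chunks[[i]])
  }
  payloads[[mname]] <- list(task = payload$task, component = comp,
                            kind = "merge", parent = task_name,
                            children = child_names)
  new_workflow_graph(nodes, new_edges, payloads)
}

chunk_output_path <- function(path, chunk_id) paste0(path, ".", chunk_id)

merge_command_for <- function(strategy, inputs, output) {
  ins <- paste(shQuote(inputs), collapse = " ")
  out <- shQuote(output)
  if (identical(strategy, "concat")) {
    sprintf("cat %s > %s", ins, out)
  } else if (identical(strategy, "concat_skip_header")) {
    sprintf("awk 'FNR==1 && NR!=1 {next} {print}' %s > %s", ins, out)
  } else {
    cmd <- gsub("{INPUTS}", ins, strategy, fixed = TRUE)
    gsub("{OUTPUT}", out, cmd, fixed = TRUE)
  }
}

## ---- parameter resolution ----------------------------------------------------

is_abs_path <- function(p) grepl("^(/|~)", p)

# resolve a task's parameter values against the workspace: interpolate
# keywords, follow IO-connections into upstream resolved values, and place
# relative output_file values under outputs/<output_dir_name or task name>/
resolve_task_params <- function(task_name, task, comp, ws, ctx, resolved) {
  out_dir_name <- task$output_dir_name %||% task_name
  out_dir_name <- interpolate_keywords(out_dir_name, ctx)
  values <- list()
  for (p in comp$params) {
    v <- task$params[[p$name]]
    if (is.null(v) || identical(v, OPTIONAL_PLACEHOLDER)) v <- p$default
    if (is.null(v)) next
    resolve1 <- function(e) {
      if (is_io_connection(e)) {
        up <- resolved[[e$source_task]][[e$source_param]]
        if (is.null(up)) {
          abort_validation(sprintf(
            "%s.%s: IO-connection to %s.%s, which resolves to no value",
            task_name, p$name, e$source_task, e$source_param))
        }
        up
      } else if (is.character(e)) {
        interpolate_keywords(e, ctx)
      } else e
    }
    v <- if (is.list(v) && !is_io_connection(v)) {
      as.character(unlist(lapply(v, resolve1)))
    } else resolve1(v)
    if (p$role == "output_file" && is.character(v)) {
      v <- ifelse(is_abs_path(v), v, file.path(ws$outputs_dir, out_dir_name, v))
    }
    values[[p$name]] <- v
  }
  values
}

## ---- sentinels ----------------------------------------------------------------

# hash identifying one task invocation, normalized by the run root (so a
# relocated workspace still resumes) and by the artifact root (so
# recompiling an edited configuration into a fresh artifact invalidates
# only what actually changed). Chained over io-edge predecessor hashes
# (Merkle-style): a changed upstream command changes every data-flow
# descendant's hash, which is what makes "rerun exactly the descendants"
# work. Forced-dependency predecessors carry no data and are excluded.
node_hash <- function(command, run_root, artifact_root, version,
                      pred_hashes = character()) {
  norm <- gsub(run_root, WSROOT_TOKEN, command, fixed = TRUE)
  norm <- gsub(artifact_root, "__ARTIFACT__", norm, fixed = TRUE)
  hash_string(c(norm, version, sort(unname(pred_hashes))))
}

sentinel_path <- function(ws, node) file.path(ws$sentinels_dir, paste0(node, ".ok"))

sentinel_matches <- function(ws, node, hash) {
  f <- sentinel_path(ws, node)
  file.exists(f) && identical(readLines(f, n = 1L, warn = FALSE), hash)
}

write_sentinel <- function(ws, node, hash) {
  f <- sentinel_path(ws, node)
  tmp <- paste0(f, ".tmp")
  writeLines(c(hash, format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")), tmp)
  file.rename(tmp, f)  # atomic: a crash never leaves a half-written sentinel
  invisible(f)
}

## ---- per-sample execution -------------------------------------------------------

log_event <- function(ws, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), msg)
  cat(line, "\n", sep = "", file = file.path(ws$logs_dir, "_run.log"), append = TRUE)
}

# assemble per-node invocation info (command, resources, breakpoint flag)
# for every node of the possibly chunk-expanded graph
node_invocations <- function(graph, resolved, ws, general) {
  invocations <- list()
  for (node in graph$nodes) {
    p <- graph$payload[[node]]
    comp <- p$component
    task <- p$task
    kind <- p$kind %||% "task"
    ro <- task$run_options
    resources <- list(
      memory = ro$memory %||% comp$requirements$memory %||%
        general$default_memory %||% "1G",
      num_cpus = ro$num_cpus %||% comp$requirements$num_cpus %||%
        general$default_num_cpus %||% 1L)
    parent <- p$parent %||% node
    values <- resolved[[parent]]
    if (kind == "chunk") {
      values[[comp$parallelization$split_param]] <- p$chunk$value
      for (ps in comp$params) {
        if (ps$role == "output_file" && !is.null(values[[ps$name]])) {
          values[[ps$name]] <- chunk_output_path(values[[ps$name]], p$chunk$chunk_id)
        }
      }
      command <- build_command(comp, values, boilerplate = ro$boilerplate)
      breakpoint <- FALSE
    } else if (kind == "merge") {
      cmds <- character()
      for (ps in comp$params) {
        if (ps$role == "output_file" && !is.null(values[[ps$name]])) {
          chunk_ids <- vapply(p$children, function(cn)
            graph$payload[[cn]]$chunk$chunk_id, "")
          inputs <- chunk_output_path(values[[ps$name]], chunk_ids)
          cmds <- c(cmds, merge_command_for(comp$parallelization$merge_strategy,
                                            inputs, values[[ps$name]]))
        }
      }
      command <- paste(cmds, collapse = " && ")
      breakpoint <- isTRUE(ro$breakpoint)
    } else {
      command <- build_command(comp, values, boilerplate = ro$boilerplate)
      breakpoint <- isTRUE(ro$breakpoint)
    }
    out_paths <- unlist(lapply(comp$params, function(ps) {
      if (ps$role == "output_file") values[[ps$name]] else NULL
    }), use.names = FALSE) %||% character()
    invocations[[node]] <- list(
      node = node, component = comp$name, version = comp$version,
      command = command, resources = resources, breakpoint = breakpoint,
      use_cluster = isTRUE(ro$use_cluster), out_dirs = unique(dirname(out_paths)))
  }
  invocations
}

write_task_script <- function(ws, node, inv) {
  script <- file.path(ws$scripts_dir, paste0(node, ".sh"))
  mkdirs <- if (length(inv$out_dirs)) {
    sprintf("mkdir -p %s", paste(shQuote(inv$out_dirs), collapse = " "))
  }
  writeLines(c("#!/bin/bash", "set -e", "set -o pipefail", mkdirs, inv$command),
             script)
  script
}

run_sample <- function(compiled, sid, sub_config, ws, run_id, backend,
                       num_jobs, halt_on_first_failure) {
  registry <- compiled$registry
  graph <- build_graph(sub_config, registry)
  # resolve original tasks in dependency order
  topo <- unlist(build_plan(graph)$stages)
  resolved <- list()
  for (tn in topo) {
    p <- graph$payload[[tn]]
    ctx <- keyword_context(run_id, compiled$name, sid, tn)
    resolved[[tn]] <- resolve_task_params(tn, p$task, p$component, ws, ctx, resolved)
  }
  # scatter parallelizable tasks
  for (tn in topo) {
    p <- graph$payload[[tn]]
    ro <- p$task$run_options
    if (isTRUE(ro$parallel_run)) {
      src <- ro$interval_source
      if (is.character(src)) {
        src <- interpolate_keywords(src, keyword_context(run_id, compiled$name, sid, tn))
      }
      chunks <- derive_chunks(src, tn, ws)
      graph <- parallelize_task(graph, tn, chunks)
    }
  }
  plan <- build_plan(graph)
  invocations <- node_invocations(graph, resolved, ws, compiled$config$general)
  # invocation hashes, chained over io-edge predecessors (dependency order)
  hashes <- list()
  for (node in unlist(plan$stages)) {
    preds <- predecessors(graph, node, kind = "io")
    hashes[[node]] <- node_hash(invocations[[node]]$command, ws$root,
                                compiled$path, invocations[[node]]$version,
                                unlist(hashes[preds]))
  }
  nodes <- unlist(plan$stages)
  status <- stats::setNames(rep("not_started", length(nodes)), nodes)
  t_start <- t_end <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  exit_code <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  stage_no <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  local_bk <- local_backend()
  paused <- FALSE
  for (si in seq_along(plan$stages)) {
    stage <- plan$stages[[si]]
    stage_no[stage] <- si
    for (node in stage) {
      preds <- predecessors(graph, node)
      if (length(preds) && !all(status[preds] %in% c("done", "skipped"))) {
        status[node] <- "blocked"
        log_event(ws, sprintf("%s blocked: upstream failure", node))
      } else if (sentinel_matches(ws, node, hashes[[node]])) {
        status[node] <- "skipped"
        log_event(ws, sprintf("%s skipped: sentinel up to date", node))
      } else {
        status[node] <- "pending"
      }
    }
    to_run <- stage[status[stage] == "pending"]
    if (length(to_run)) {
      run_one <- function(node) {
        inv <- invocations[[node]]
        script <- write_task_script(ws, node, inv)
        log <- file.path(ws$logs_dir, paste0(node, ".log"))
        bk <- if (backend$universal || inv$use_cluster) backend else local_bk
        t0 <- as.numeric(Sys.time())
        code <- bk$run(script, log, inv$resources)
        t1 <- as.numeric(Sys.time())
        list(node = node, code = code, t0 = t0, t1 = t1)
      }
      for (node in to_run) log_event(ws, sprintf("%s started", node))
      results <- if (length(to_run) > 1L && num_jobs > 1L) {
        parallel::mclapply(to_run, run_one, mc.cores = min(num_jobs, length(to_run)),
                           mc.preschedule = FALSE)
      } else {
        lapply(to_run, run_one)
      }
      for (r in results) {
        if (inherits(r, "try-error") || is.null(r$code)) {
          status[r$node %||% to_run[1]] <- "failed"
          next
        }
        t_start[r$node] <- r$t0; t_end[r$node] <- r$t1
        exit_code[r$node] <- r$code
        if (r$code == 0L) {
          status[r$node] <- "done"
          write_sentinel(ws, r$node, hashes[[r$node]])
          log_event(ws, sprintf("%s finished (exit 0)", r$node))
        } else {
          status[r$node] <- "failed"
          log_event(ws, sprintf("%s FAILED (exit %d)", r$node, r$code))
        }
      }
      if (any(status[to_run] == "failed") && halt_on_first_failure) break
      # a breakpoint pauses the run after its task completes in this
      # invocation; a breakpoint task skipped via sentinel does not re-pause
      bp_hit <- any(vapply(to_run, function(n)
        invocations[[n]]$breakpoint && status[n] == "done", logical(1)))
      if (bp_hit) { paused <- TRUE; break }
    }
  }
  report <- data.frame(
    sample = sid, task = nodes,
    component = vapply(invocations[nodes], `[[`, "", "component"),
    status = unname(status[nodes]), stage = unname(stage_no[nodes]),
    started = unname(t_start[nodes]), finished = unname(t_end[nodes]),
    exit_code = unname(exit_code[nodes]),
    stringsAsFactors = FALSE)
  sample_status <- if (any(report$status %in% c("failed", "blocked"))) "failed"
    else if (paused || any(report$status == "not_started")) "paused"
    else "completed"
  jsonlite::write_json(list(run_id = run_id, sample = sid, status = sample_status,
                            tasks = report),
                       file.path(ws$root, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(report = report, status = sample_status)
}

## ---- top-level execution ---------------------------------------------------------

#' Execute a compiled workflow
#'
#' Runs every per-sample sub-workflow of a compiled workflow: builds the
#' task DAG, scatters parallelizable tasks over chunks, plans concurrent
#' stages, and runs them — writing each task's rendered script to
#' `scripts/`, streaming its output to `logs/`, and dropping a sentinel in
#' `sentinels/` on success. Tasks whose sentinel matches the current
#' invocation hash are skipped, so re-executing a finished run performs
#' zero submissions and re-executing after a parameter edit reruns exactly
#' the changed task and its data-flow descendants. A failed task blocks its
#' dependents while independent branches continue (pass
#' `halt_on_first_failure = TRUE` for the stricter policy). A task marked
#' `breakpoint: true` pauses the run after completing; a later invocation
#' with `resume` picks up the remainder, possibly from a relocated
#' workspace root.
#'
#' @param compiled a `compiled_workflow` from [init_workflow()] or
#'   [load_workflow()].
#' @param backend an `executor_backend`; tasks with `use_cluster: true` are
#'   submitted here, the rest run on [local_backend()] (universal backends
#'   — local, noop — take everything).
#' @param num_jobs maximum number of concurrently running tasks.
#' @param out_root directory holding run trees; defaults to `runs/` inside
#'   the workflow artifact.
#' @param run_id explicit run-ID for a fresh run (normally generated).
#' @param resume run-ID of a previous run to pick up.
#' @param halt_on_first_failure stop scheduling after the first failure
#'   instead of continuing independent branches.
#' @return a `run_report` with overall `status` (`"completed"`, `"paused"`
#'   or `"failed"`), per-task rows (status, stage, timestamps, exit codes)
#'   and the workspace location. A JSON copy is written into the run tree.
#' @export
execute_workflow <- function(compiled, backend = local_backend(), num_jobs = 1L,
                             out_root = NULL, run_id = NULL, resume = NULL,
                             halt_on_first_failure = FALSE) {
  stopifnot(inherits(compiled, "compiled_workflow"),
            inherits(backend, "executor_backend"))
  out_root <- out_root %||% file.path(compiled$path, "runs")
  resuming <- !is.null(resume)
  if (resuming) {
    run_id <- resume
    if (!dir.exists(file.path(out_root, run_id))) {
      abort_validation(sprintf("cannot resume: no run '%s' under '%s'", run_id, out_root))
    }
  } else {
    run_id <- run_id %||% new_run_id()
    if (dir.exists(file.path(out_root, run_id))) {
      abort_validation(sprintf(
        "run directory '%s' already exists; pass resume = \"%s\" to pick it up",
        file.path(out_root, run_id), run_id))
    }
  }
  sample_ids <- names(compiled$sub_workflows)
  state <- create_run_workspace(out_root, run_id,
                                if (identical(sample_ids, "run")) character() else sample_ids)
  run1 <- function(sid, jobs) {
    run_sample(compiled, sid, compiled$sub_workflows[[sid]],
               state$workspaces[[sid]], run_id, backend, jobs,
               halt_on_first_failure)
  }
  sids <- names(state$workspaces)
  results <- if (length(sids) > 1L && num_jobs > 1L) {
    # sweep sub-workflows run concurrently, one worker per sample
    parallel::mclapply(sids, run1, jobs = 1L,
                       mc.cores = min(num_jobs, length(sids)),
                       mc.preschedule = FALSE)
  } else {
    lapply(sids, run1, jobs = num_jobs)
  }
  names(results) <- sids
  tasks <- do.call(rbind, lapply(results, `[[`, "report"))
  rownames(tasks) <- NULL
  statuses <- vapply(results, `[[`, "", "status")
  overall <- if (any(statuses == "failed")) "failed"
    else if (any(statuses == "paused")) "paused" else "completed"
  jsonlite::write_json(
    list(run_id = run_id, workflow = compiled$name, status = overall,
         samples = as.list(statuses)),
    file.path(state$root, "index.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  structure(list(run_id = run_id, workflow = compiled$name, status = overall,
                 root = state$root, sample_status = statuses, tasks = tasks),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s  run-ID %s  status: %s\n",
              x$workflow, x$run_id, x$status))
  counts <- table(x$tasks$status)
  cat(" ", paste(sprintf("%s=%d", names(counts), counts), collapse = "  "), "\n")
  invisible(x)
}

#' Set a breakpoint on a task of a compiled workflow
#'
#' Marks `task_name` so that [execute_workflow()] pauses — status
#' `"paused"` — after that task (and everything scheduled at or before its
#' stage) completes. A later `resume` invocation runs only the remainder,
#' enabling controlled inspection between subworkflows or moving the run to
#' another machine (with the intermediate files present).
#'
#' @param compiled a `compiled_workflow`.
#' @param task_name an existing task section name.
#' @return the modified `compiled_workflow`.
#' @export
apply_breakpoint <- function(compiled, task_name) {
  stopifnot(inherits(compiled, "compiled_workflow"))
  if (!task_name %in% names(compiled$config$tasks)) {
    abort_validation(sprintf("breakpoint on unknown task %s", task_name))
  }
  compiled$config$tasks[[task_name]]$run_options$breakpoint <- TRUE
  for (sid in names(compiled$sub_workflows)) {
    compiled$sub_workflows[[sid]]$tasks[[task_name]]$run_options$breakpoint <- TRUE
  }
  compiled
}
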