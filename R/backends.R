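# Executor backends: how one rendered task script actually gets run.
# The contract is a single blocking call; the engine owns ordering and
# concurrency, so a backend must never reorder dependent submissions —
# it only ever sees one script at a time. Exit status 0 means success.

new_backend <- function(name, run, universal = FALSE) {
  structure(list(name = name, run = run, universal = universal),
            class = "executor_backend")
}

#' @export
print.executor_backend <- function(x, ...) {
  cat(sprintf("<executor_backend> %s\n", x$name)); invisible(x)
}

#' Local executor backend
#'
#' Runs each task script with `bash`, streaming stdout and stderr to the
#' task's log file. Concurrency across independent tasks is handled by the
#' engine through a bounded worker pool of size `num_jobs`.
#'
#' @return an `executor_backend`.
#' @export
local_backend <- function() {
  new_backend("local", universal = TRUE, run = function(script, log, resources) {
    status <- system2("bash", shQuote(script), stdout = log, stderr = log)
    as.integer(status)
  })
}

#' Generic batch-submission backend
#'
#' Reference cluster backend: shells out to a user-supplied submit-command
#' template instead of baking in any scheduler-specific code. The template
#' may contain the placeholders `{SCRIPT}`, `{LOG}`, `{MEMORY}` and
#' `{NUM_CPUS}`; the rendered command must block until the job finishes and
#' propagate its exit status (e.g. `qsub -sync y` style submission, or a
#' plain `bash {SCRIPT}` for testing). Only tasks whose run options set
#' `use_cluster: true` are routed here; others run on [local_backend()].
#'
#' @param submit_template submit command template string.
#' @return an `executor_backend`.
#' @export
shell_backend <- function(submit_template) {
  stopifnot(is_string(submit_template))
  new_backend("shell", universal = FALSE, run = function(script, log, resources) {
    cmd <- submit_template
    subs <- c(SCRIPT = script, LOG = log,
              MEMORY = resources$memory %||% "1G",
              NUM_CPUS = as.character(resources$num_cpus %||% 1L))
    for (k in names(subs)) {
      cmd <- gsub(paste0("{", k, "}"), subs[[k]], cmd, fixed = TRUE)
    }
    if (!grepl("\\{LOG\\}", submit_template)) {
      cmd <- sprintf("%s > %s 2>&1", cmd, shQuote(log))
    }
    as.integer(system(cmd))
  })
}

#' Dry-run backend
#'
#' Executes nothing: every submission immediately succeeds and an empty log
#' is touched. Scheduling, workspace creation, sentinel writing, timestamps
#' and reports all behave exactly as in a real run, which makes this backend
#' the tool for inspecting what a workflow *would* do and for exercising the
#' engine's ordering guarantees cheaply.
#'
#' @return an `executor_backend`.
#' @export
noop_backend <- function() {
  new_backend("noop", universal = TRUE, run = function(script, log, resources) {
    file.create(log)
    0L
  })
}
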