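# The YAML workflow configuration language: five top-level blocks
# (GENERAL, PIPELINE_INFO, SHARED, SAMPLES, __TASK_*__ sections), with
# IO-connections wiring one task's input parameter to another task's output.

## ---- value references -------------------------------------------------

#' IO-connection: wire a task input to another task's output
#'
#' An IO-connection is a (task name, parameter name) pair given as the value
#' of one of the consuming task's parameters. It both supplies the data path
#' and orders the two tasks in the workflow DAG. In configuration files it is
#' written either as the quoted tuple string `('__TASK_1__', 'out_file')` or
#' as a two-element YAML flow list `[__TASK_1__, out_file]`.
#'
#' @param source_task name of the producing task section.
#' @param source_param parameter of the producing task whose value flows in.
#' @return an object of class `io_connection`.
#' @export
io_connection <- function(source_task, source_param) {
  stopifnot(is_string(source_task), is_string(source_param))
  structure(list(source_task = source_task, source_param = source_param),
            class = "io_connection")
}

#' @export
print.io_connection <- function(x, ...) {
  cat(sprintf("('%s', '%s')\n", x$source_task, x$source_param))
  invisible(x)
}

is_io_connection <- function(x) inherits(x, "io_connection")

shared_ref <- function(key) structure(list(key = key), class = "shared_ref")
sample_ref <- function(key) structure(list(key = key), class = "sample_ref")
is_shared_ref <- function(x) inherits(x, "shared_ref")
is_sample_ref <- function(x) inherits(x, "sample_ref")

# Tuple-string form: exactly two quoted elements, e.g. "('__A__', 'out')".
# One- and three-element tuples deliberately do not match and stay literal.
TUPLE_RE <- "^\\(\\s*['\"]([^'\"]+)['\"]\\s*,\\s*['\"]([^'\"]+)['\"]\\s*\\)$"

parse_tuple_string <- function(x) {
  if (!is_string(x) || !grepl(TUPLE_RE, x)) return(NULL)
  m <- regmatches(x, regexec(TUPLE_RE, x))[[1]]
  make_ref(m[2], m[3])
}

make_ref <- function(source, key) {
  if (identical(source, "__SHARED__")) return(shared_ref(key))
  if (identical(source, "__SAMPLES__")) return(sample_ref(key))
  io_connection(source, key)
}

# Recognize IO-connections in a raw YAML value and normalize. Accepted forms:
#   * tuple string "('__TASK_1__', 'out_file')"
#   * two-element list/vector whose first element is a dunder name
#   * a list of tuple strings (fan-in: several outputs feed one parameter)
# Everything else is a literal.
parse_param_value <- function(v) {
  if (is.character(v)) {
    tuples <- lapply(v, parse_tuple_string)
    if (length(v) >= 1L && !any(vapply(tuples, is.null, logical(1)))) {
      return(if (length(tuples) == 1L) tuples[[1]] else tuples)
    }
    if (length(v) == 2L && grepl(TASK_NAME_RE, v[[1]]) ||
        (length(v) == 2L && v[[1]] %in% c("__SHARED__", "__SAMPLES__"))) {
      return(make_ref(v[[1]], v[[2]]))
    }
    return(if (length(v) == 1L) v[[1]] else v)
  }
  if (is.list(v) && length(v) == 2L && is.null(names(v)) &&
      all(vapply(v, is_string, logical(1))) &&
      (grepl(TASK_NAME_RE, v[[1]]) || v[[1]] %in% c("__SHARED__", "__SAMPLES__"))) {
    return(make_ref(v[[1]], v[[2]]))
  }
  if (is.list(v) && length(v) >= 1L && is.null(names(v))) {
    tuples <- lapply(v, function(el) if (is_string(el)) parse_tuple_string(el) else NULL)
    if (!any(vapply(tuples, is.null, logical(1)))) return(tuples)
  }
  v
}

## ---- task sections -----------------------------------------------------

TASK_RESERVED_KEYS <- c("component", "run", "forced_dependencies", "output_dir_name")

default_run_options <- function() {
  list(use_cluster = FALSE, memory = NULL, num_cpus = NULL,
       parallel_run = FALSE, interval_source = NULL, boilerplate = NULL,
       breakpoint = FALSE)
}

new_task_section <- function(component_name, params = list(),
                             run_options = default_run_options(),
                             forced_dependencies = character(),
                             output_dir_name = NULL, extra_keys = character()) {
  structure(list(component_name = component_name, params = params,
                 run_options = run_options,
                 forced_dependencies = forced_dependencies,
                 output_dir_name = output_dir_name,
                 extra_keys = extra_keys),
            class = "task_section")
}

parse_task_section <- function(name, x) {
  if (!is.list(x)) {
    abort_validation(sprintf("task section %s must be a YAML mapping", name))
  }
  ro <- default_run_options()
  raw_run <- x[["run"]] %||% list()
  extra <- setdiff(names(raw_run), names(ro))
  for (k in intersect(names(raw_run), names(ro))) ro[[k]] <- raw_run[[k]]
  param_keys <- setdiff(names(x), TASK_RESERVED_KEYS)
  params <- lapply(x[param_keys], parse_param_value)
  names(params) <- param_keys
  new_task_section(
    component_name = x[["component"]] %||% NA_character_,
    params = params,
    run_options = ro,
    forced_dependencies = as.character(unlist(x[["forced_dependencies"]]) %||% character()),
    output_dir_name = x[["output_dir_name"]],
    extra_keys = if (length(extra)) paste0("run.", extra) else character()
  )
}

## ---- workflow configuration ---------------------------------------------

new_workflow_config <- function(general = list(), pipeline_info = list(),
                                shared = list(), samples = list(),
                                tasks = list()) {
  structure(list(general = general, pipeline_info = pipeline_info,
                 shared = shared, samples = samples, tasks = tasks),
            class = "workflow_config")
}

#' Parse a workflow configuration file
#'
#' Reads the YAML text of a workflow configuration into a `workflow_config`
#' object. The file holds up to four fixed blocks — `GENERAL` and
#' `PIPELINE_INFO` (system-specific), `SHARED` and `SAMPLES` (user-specific)
#' — plus one `__TASK_*__` section per task (workflow-specific). Missing
#' blocks become empty. IO-connection values in either accepted concrete
#' syntax are normalized to [io_connection()] objects; `('__SHARED__', key)`
#' and `('__SAMPLES__', key)` values become references resolved later by
#' [expand_samples()].
#'
#' @param yaml_text configuration as a single string, or a character vector
#'   of lines.
#' @return a `workflow_config` with fields `general`, `pipeline_info`,
#'   `shared`, `samples` (ordered, possibly empty) and `tasks` (ordered
#'   named list of task sections).
#' @seealso [validate_config()], [make_config_template()]
#' @examples
#' cfg <- parse_config("
#' __TASK_1__:
#'   component: comp_textgen
#'   out_file: foo.txt
#' __TASK_2__:
#'   component: comp_copy
#'   in_file: ('__TASK_1__', 'out_file')
#'   out_file: bar.txt
#' ")
#' names(cfg$tasks)
#' @export
parse_config <- function(yaml_text) {
  txt <- paste(yaml_text, collapse = "\n")
  doc <- tryCatch(
    ff_yaml_load(txt),
    error = function(e) {
      abort_validation(paste0("configuration YAML parse error: ",
                              conditionMessage(e)))
    }
  )
  if (is.null(doc)) doc <- list()
  if (!is.list(doc) || (length(doc) && is.null(names(doc)))) {
    abort_validation("configuration must be a YAML mapping of sections")
  }
  nm <- names(doc)
  is_task <- grepl(TASK_NAME_RE, nm) & !nm %in% c("__SHARED__", "__SAMPLES__")
  unknown <- nm[!is_task & !nm %in% RESERVED_SECTION_NAMES]
  if (length(unknown)) {
    abort_validation(sprintf("unknown top-level section(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  tasks <- lapply(nm[is_task], function(tn) parse_task_section(tn, doc[[tn]]))
  names(tasks) <- nm[is_task]
  samples <- doc[["SAMPLES"]] %||% list()
  if (length(samples) && (!is.list(samples) || is.null(names(samples)))) {
    abort_validation("SAMPLES must be a mapping of sample_id -> parameter map")
  }
  new_workflow_config(
    general = doc[["GENERAL"]] %||% list(),
    pipeline_info = doc[["PIPELINE_INFO"]] %||% list(),
    shared = doc[["SHARED"]] %||% list(),
    samples = samples,
    tasks = tasks
  )
}

#' @export
print.workflow_config <- function(x, ...) {
  cat(sprintf("<workflow_config> %d task(s), %d sample(s)\n",
              length(x$tasks), length(x$samples)))
  for (tn in names(x$tasks)) {
    cat(sprintf("  %s (%s)\n", tn, x$tasks[[tn]]$component_name))
  }
  invisible(x)
}

## ---- template generation -------------------------------------------------

#' Generate a configuration file template from components
#'
#' Emits a YAML configuration template with one `__TASK_i__` section per
#' component, in input order, mostly prefilled: every component parameter
#' appears with its declared default or an explicit `__REQUIRED__` /
#' `__OPTIONAL__` placeholder, and skeleton `GENERAL`, `PIPELINE_INFO`,
#' `SHARED` and `SAMPLES` blocks are included. The user then wires tasks
#' together by replacing input placeholders with IO-connections.
#'
#' @param components ordered list of `component_definition` objects
#'   (see [load_component()]); a component may appear more than once, giving
#'   distinct task sections backed by the same component.
#' @param pipeline_name,author strings written into `PIPELINE_INFO`.
#' @return the template as a single YAML string, parseable by
#'   [parse_config()].
#' @export
make_config_template <- function(components, pipeline_name = "workflow",
                                 author = "unknown") {
  if (!length(components)) stop("component list must be non-empty")
  if (inherits(components, "component_definition")) components <- list(components)
  doc <- list(
    GENERAL = list(default_memory = "1G", default_num_cpus = 1L),
    PIPELINE_INFO = list(name = pipeline_name, version = "1.0", author = author),
    SHARED = list(),
    SAMPLES = list()
  )
  for (i in seq_along(components)) {
    comp <- components[[i]]
    stopifnot(inherits(comp, "component_definition"))
    sec <- list(
      component = comp$name,
      run = list(use_cluster = FALSE,
                 memory = comp$requirements$memory,
                 num_cpus = comp$requirements$num_cpus,
                 parallel_run = FALSE),
      forced_dependencies = list()
    )
    for (p in comp$params) {
      sec[[p$name]] <- if (!is.null(p$default)) {
        p$default
      } else if (isTRUE(p$required)) REQUIRED_PLACEHOLDER else OPTIONAL_PLACEHOLDER
    }
    doc[[sprintf("__TASK_%d__", i)]] <- sec
  }
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
}

## ---- validation ----------------------------------------------------------

new_diag <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a workflow configuration
#'
#' Runs all static checks a configuration must pass before it can be
#' compiled: task-name syntax, component resolution, declared-parameter and
#' IO-connection integrity (dangling task or parameter references,
#' self-connections), forced-dependency references and self-loops, cycle
#' detection over the implied DAG, SHARED/SAMPLES reference resolution,
#' required parameters left unfilled, resource sanity, and the
#' parallelization contract.
#'
#' @param config a `workflow_config` from [parse_config()].
#' @param components optional component registry (named list from
#'   [load_components()]); component-level checks are skipped when absent.
#' @return a `workflow_diagnostics` data frame with columns `severity`
#'   (`"error"` or `"warning"`), `location` and `message`, ordered by task.
#'   A config is compilable iff it produces zero rows of severity `"error"`.
#' @export
validate_config <- function(config, components = NULL) {
  stopifnot(inherits(config, "workflow_config"))
  d <- new_diag(character(), character(), character())
  add <- function(severity, location, message) {
    d <<- rbind(d, new_diag(severity, location, message))
  }
  tns <- names(config$tasks)
  if (anyDuplicated(tns)) {
    add("error", "tasks", sprintf("duplicate task name(s): %s",
                                  paste(unique(tns[duplicated(tns)]), collapse = ", ")))
  }
  sample_keys_seen <- character()
  for (tn in tns) {
    task <- config$tasks[[tn]]
    loc <- tn
    if (!grepl(TASK_NAME_RE, tn)) {
      add("error", loc, "task name must match the __NAME__ identifier pattern")
    }
    comp <- NULL
    if (is.na(task$component_name)) {
      add("error", loc, "task section has no 'component' entry")
    } else if (!is.null(components)) {
      comp <- components[[task$component_name]]
      if (is.null(comp)) {
        add("error", loc, sprintf("unknown component '%s'", task$component_name))
      }
    }
    if (length(task$extra_keys)) {
      add("warning", loc, sprintf("unknown run option(s): %s",
                                  paste(task$extra_keys, collapse = ", ")))
    }
    ro <- task$run_options
    if (!is.null(ro$memory) && !grepl("^[0-9]+(\\.[0-9]+)?[KMGT]?B?$", ro$memory)) {
      add("error", loc, sprintf("invalid memory request '%s'", ro$memory))
    }
    if (!is.null(ro$num_cpus) && (!is.numeric(ro$num_cpus) || ro$num_cpus < 1)) {
      add("error", loc, "num_cpus must be a positive integer")
    }
    if (isTRUE(ro$parallel_run)) {
      if (!is.null(comp) && is.null(comp$parallelization)) {
        add("error", loc, sprintf(
          "parallel_run requested but component '%s' declares no parallelization contract",
          task$component_name))
      }
      if (is.null(ro$interval_source)) {
        add("error", loc, "parallel_run requires an interval_source (BED file or shard count)")
      }
    }
    for (fd in task$forced_dependencies) {
      if (identical(fd, tn)) {
        add("error", loc, sprintf("self-dependency: %s forces a dependency on itself", tn))
      } else if (!fd %in% tns) {
        add("error", loc, sprintf("forced dependency on nonexistent task %s", fd))
      }
    }
    declared <- if (!is.null(comp)) vapply(comp$params, `[[`, "", "name") else NULL
    for (pn in names(task$params)) {
      v <- task$params[[pn]]
      ploc <- sprintf("%s.%s", tn, pn)
      if (!is.null(declared) && !pn %in% declared) {
        add("warning", ploc, sprintf("parameter '%s' is not declared by component '%s'",
                                     pn, task$component_name))
      }
      conns <- if (is_io_connection(v)) list(v) else if (is.list(v))
        Filter(is_io_connection, v) else list()
      for (conn in conns) {
        if (identical(conn$source_task, tn)) {
          add("error", ploc, "self-connection: a task cannot consume its own output")
        } else if (!conn$source_task %in% tns) {
          add("error", ploc, sprintf(
            "IO-connection references nonexistent task %s (consumed by %s)",
            conn$source_task, ploc))
        } else if (!is.null(components)) {
          src <- components[[config$tasks[[conn$source_task]]$component_name]]
          if (!is.null(src) &&
              !conn$source_param %in% vapply(src$params, `[[`, "", "name")) {
            add("error", ploc, sprintf(
              "IO-connection references parameter '%s' not declared by task %s",
              conn$source_param, conn$source_task))
          }
        }
      }
      refs <- if (is_shared_ref(v) || is_sample_ref(v)) list(v) else if (is.list(v))
        Filter(function(e) is_shared_ref(e) || is_sample_ref(e), v) else list()
      for (r in refs) {
        if (is_shared_ref(r) && !r$key %in% names(config$shared)) {
          add("error", ploc, sprintf("SHARED reference to missing key '%s'", r$key))
        }
        if (is_sample_ref(r)) {
          sample_keys_seen <- c(sample_keys_seen, r$key)
          missing_in <- names(config$samples)[!vapply(
            config$samples, function(s) r$key %in% names(s), logical(1))]
          if (length(config$samples) && length(missing_in)) {
            add("error", ploc, sprintf(
              "SAMPLES reference to key '%s' missing in sample(s): %s",
              r$key, paste(missing_in, collapse = ", ")))
          }
        }
      }
      if (identical(v, REQUIRED_PLACEHOLDER)) {
        add("error", ploc, "required parameter placeholder left unfilled")
      }
    }
    if (!is.null(comp)) {
      req <- vapply(comp$params, function(p) isTRUE(p$required), logical(1))
      have_default <- vapply(comp$params, function(p) !is.null(p$default), logical(1))
      req_names <- vapply(comp$params, `[[`, "", "name")[req & !have_default]
      missing <- setdiff(req_names, names(task$params))
      for (pn in missing) {
        add("error", loc, sprintf("required parameter '%s' of component '%s' not set",
                                  pn, task$component_name))
      }
    }
  }
  # ragged sweep detection
  if (length(config$samples) > 1L) {
    all_keys <- unique(unlist(lapply(config$samples, names)))
    for (sid in names(config$samples)) {
      missing <- setdiff(all_keys, names(config$samples[[sid]]))
      if (length(missing)) {
        add("error", sprintf("SAMPLES.%s", sid),
            sprintf("ragged sweep: sample lacks key(s) %s present in other samples",
                    paste(missing, collapse = ", ")))
      }
    }
  }
  # cycle check over io + forced edges (restricted to existing endpoints)
  edges <- config_edges(config)
  edges <- edges[edges$from %in% tns & edges$to %in% tns & edges$from != edges$to, ,
                 drop = FALSE]
  cyc <- find_cycle(tns, edges)
  if (!is.null(cyc)) {
    add("error", "tasks", sprintf("dependency cycle: %s", paste(cyc, collapse = " -> ")))
  }
  # two tasks writing the same literal output path: warn rather than
  # auto-serialize — a forced dependency is the supported remedy
  if (!is.null(components)) {
    outs <- unlist(lapply(tns, function(tn) {
      task <- config$tasks[[tn]]
      comp <- components[[task$component_name]]
      if (is.null(comp)) return(NULL)
      out_params <- vapply(comp$params, `[[`, "", "name")[
        vapply(comp$params, function(p) p$role == "output_file", logical(1))]
      vals <- task$params[intersect(out_params, names(task$params))]
      unlist(Filter(is_string, vals))
    }))
    dup <- unique(outs[duplicated(outs)])
    if (length(dup)) {
      add("warning", "tasks",
          sprintf("multiple tasks declare the same output path: %s; add a forced dependency to serialize them",
                  paste(dup, collapse = ", ")))
    }
  }
  class(d) <- c("workflow_diagnostics", class(d))
  d
}

#' @export
print.workflow_diagnostics <- function(x, ...) {
  if (!nrow(x)) {
    cat("no diagnostics: configuration is compilable\n")
  } else {
    cat(sprintf("%s: %s: %s", x$severity, x$location, x$message), sep = "\n")
  }
  invisible(x)
}

config_errors <- function(diags) diags[diags$severity == "error", , drop = FALSE]

stop_on_errors <- function(diags) {
  errs <- config_errors(diags)
  if (nrow(errs)) {
    abort_validation(paste0("configuration is not compilable:\n",
                            paste(sprintf("  error: %s: %s", errs$location, errs$message),
                                  collapse = "\n")),
                     diagnostics = diags)
  }
  invisible(diags)
}

# all dependency edges implied by a config: io connections + forced deps
config_edges <- function(config) {
  from <- character(); to <- character(); kind <- character()
  for (tn in names(config$tasks)) {
    task <- config$tasks[[tn]]
    for (v in task$params) {
      conns <- if (is_io_connection(v)) list(v) else if (is.list(v))
        Filter(is_io_connection, v) else list()
      for (conn in conns) {
        from <- c(from, conn$source_task); to <- c(to, tn); kind <- c(kind, "io")
      }
    }
    for (fd in task$forced_dependencies) {
      from <- c(from, fd); to <- c(to, tn); kind <- c(kind, "forced")
    }
  }
  data.frame(from = from, to = to, kind = kind, stringsAsFactors = FALSE)
}

## ---- parameter sweeping --------------------------------------------------

#' Expand the SAMPLES block into concrete per-sample workflows
#'
#' Parameter sweeping: each entry of `SAMPLES` holds one set of input
#' arguments; expansion yields one concrete workflow per entry, with that
#' entry's key/value pairs (and all `SHARED` values) substituted into the
#' referencing task parameters. The task structure — names and dependency
#' edges — is identical across all outputs; only parameter values differ.
#' An empty `SAMPLES` block yields a single workflow keyed `"run"`.
#'
#' @param config a validated `workflow_config`.
#' @return named list `sample_id -> workflow_config`, each concrete (no
#'   remaining SHARED/SAMPLES references, empty `samples` field).
#' @export
expand_samples <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  samples <- config$samples
  if (length(samples) > 1L) {
    all_keys <- unique(unlist(lapply(samples, names)))
    ragged <- names(samples)[vapply(samples, function(s)
      length(setdiff(all_keys, names(s))) > 0, logical(1))]
    if (length(ragged)) {
      abort_validation(sprintf("ragged sweep: sample(s) %s lack keys present in others",
                               paste(ragged, collapse = ", ")))
    }
  }
  referenced <- character()
  substitute_refs <- function(cfg, sample) {
    for (tn in names(cfg$tasks)) {
      params <- cfg$tasks[[tn]]$params
      for (pn in names(params)) {
        v <- params[[pn]]
        resolve1 <- function(e) {
          if (is_shared_ref(e)) {
            if (!e$key %in% names(cfg$shared)) {
              abort_validation(sprintf("%s.%s: SHARED reference to missing key '%s'",
                                       tn, pn, e$key))
            }
            cfg$shared[[e$key]]
          } else if (is_sample_ref(e)) {
            referenced <<- c(referenced, e$key)
            if (!e$key %in% names(sample)) {
              abort_validation(sprintf("%s.%s: SAMPLES reference to key '%s' absent from sample",
                                       tn, pn, e$key))
            }
            sample[[e$key]]
          } else e
        }
        params[[pn]] <- if (is.list(v) && !is_io_connection(v) &&
                            !is_shared_ref(v) && !is_sample_ref(v)) {
          lapply(v, resolve1)
        } else resolve1(v)
      }
      cfg$tasks[[tn]]$params <- params
    }
    cfg$samples <- list()
    cfg
  }
  out <- if (!length(samples)) {
    list(run = substitute_refs(config, list()))
  } else {
    stats::setNames(
      lapply(names(samples), function(sid) substitute_refs(config, samples[[sid]])),
      names(samples))
  }
  if (length(samples)) {
    unused <- setdiff(unique(unlist(lapply(samples, names))), unique(referenced))
    if (length(unused)) {
      warning(sprintf("sample key(s) referenced by no task: %s",
                      paste(unused, collapse = ", ")), call. = FALSE)
    }
  }
  out
}

## ---- keyword interpolation ------------------------------------------------

KEYWORD_TOKENS <- c("RUN_ID", "SAMPLE_ID", "WORKFLOW_NAME", "TASK_NAME")

#' Keyword context for run-time interpolation
#'
#' Bundles the run-time values substituted for the `$RUN_ID`, `$SAMPLE_ID`,
#' `$WORKFLOW_NAME` and `$TASK_NAME` keywords in configuration strings.
#'
#' @param run_id,workflow_name,sample_id,task_name non-empty strings.
#' @return an object of class `keyword_context`.
#' @export
keyword_context <- function(run_id, workflow_name, sample_id, task_name) {
  vals <- list(RUN_ID = run_id, WORKFLOW_NAME = workflow_name,
               SAMPLE_ID = sample_id, TASK_NAME = task_name)
  bad <- names(vals)[!vapply(vals, function(v) is_string(v) && nzchar(v), logical(1))]
  if (length(bad)) {
    stop(sprintf("keyword context field(s) empty or invalid: %s",
                 paste(tolower(bad), collapse = ", ")))
  }
  structure(vals, class = "keyword_context")
}

#' Interpolate run-time keywords into a string
#'
#' Replaces every occurrence of the four `$UPPER_SNAKE` keywords
#' (`$RUN_ID`, `$SAMPLE_ID`, `$WORKFLOW_NAME`, `$TASK_NAME`) with the values
#' in `ctx`, letting configuration authors customize paths and file names
#' from run-time values. A literal dollar sign is written `$$`. Any other
#' `$TOKEN` is an error, never silently kept. Idempotent on token-free
#' strings.
#'
#' @param template character vector to interpolate.
#' @param ctx a [keyword_context()].
#' @return `template` with all keywords substituted.
#' @export
interpolate_keywords <- function(template, ctx) {
  stopifnot(inherits(ctx, "keyword_context"), is.character(template))
  vapply(template, function(s) {
    esc <- gsub("$$", "\x01", s, fixed = TRUE)
    for (tok in KEYWORD_TOKENS) {
      esc <- gsub(paste0("$", tok), ctx[[tok]], esc, fixed = TRUE)
    }
    m <- regmatches(esc, gregexpr("\\$[A-Z][A-Z_]*", esc))[[1]]
    if (length(m)) {
      stop(sprintf("unknown keyword token(s) %s in string '%s'",
                   paste(unique(m), collapse = ", "), s))
    }
    gsub("\x01", "$", esc, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

## ---- re-emission -----------------------------------------------------------

unparse_param_value <- function(v) {
  ref_str <- function(e) {
    if (is_io_connection(e)) sprintf("('%s', '%s')", e$source_task, e$source_param)
    else if (is_shared_ref(e)) sprintf("('__SHARED__', '%s')", e$key)
    else if (is_sample_ref(e)) sprintf("('__SAMPLES__', '%s')", e$key)
    else e
  }
  if (is_io_connection(v) || is_shared_ref(v) || is_sample_ref(v)) return(ref_str(v))
  if (is.list(v)) return(lapply(v, ref_str))
  v
}

#' Serialize a workflow configuration back to YAML
#'
#' Inverse of [parse_config()]: IO-connections and SHARED/SAMPLES references
#' are rendered in the quoted-tuple syntax. `parse_config(config_to_yaml(x))`
#' reproduces `x`.
#'
#' @param config a `workflow_config`.
#' @return a single YAML string.
#' @export
config_to_yaml <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  doc <- list(GENERAL = config$general, PIPELINE_INFO = config$pipeline_info,
              SHARED = config$shared, SAMPLES = config$samples)
  for (tn in names(config$tasks)) {
    task <- config$tasks[[tn]]
    sec <- list(component = task$component_name)
    ro <- task$run_options
    sec$run <- Filter(Negate(is.null), ro)
    if (length(task$forced_dependencies)) {
      sec$forced_dependencies <- as.list(task$forced_dependencies)
    }
    if (!is.null(task$output_dir_name)) sec$output_dir_name <- task$output_dir_name
    for (pn in names(task$params)) {
      sec[[pn]] <- unparse_param_value(task$params[[pn]])
    }
    doc[[tn]] <- sec
  }
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
}
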