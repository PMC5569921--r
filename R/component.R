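# Components: reusable wrappers around command-line tools. Each component
# lives in a standard directory
#   <name>/component.yaml   declarative definition (this file IS the contract)
#   <name>/wrapper          executable stub invoking the seed
#   <name>/seed/            the wrapped tool itself (any language)
#   <name>/README.md, <name>/tests/
# and is instantiated as task sections in any number of workflows.

PARAM_ROLES <- c("input_file", "output_file", "argument", "flag")
MERGE_STRATEGIES <- c("concat", "concat_skip_header")

#' Parameter specification of a component
#'
#' @param name parameter name (unique within the component).
#' @param role one of `"input_file"`, `"output_file"`, `"argument"`,
#'   `"flag"`. Roles drive run-time path resolution: `output_file` values are
#'   placed under the task's workspace output directory, `input_file` values
#'   may be fed by IO-connections, `flag` parameters render as bare `--name`
#'   switches only when true.
#' @param required must a task supply a value (or have a default)?
#' @param default optional default value.
#' @return an object of class `param_spec`.
#' @export
param_spec <- function(name, role = "argument", required = FALSE, default = NULL) {
  stopifnot(is_string(name))
  role <- match.arg(role, PARAM_ROLES)
  structure(list(name = name, role = role, required = isTRUE(required),
                 default = default),
            class = "param_spec")
}

#' Declarative definition of one wrapped command-line tool
#'
#' @param name component name, a valid identifier (no path separators).
#' @param seed_command command template for the wrapped tool. May contain
#'   `{COMPONENT_DIR}` (replaced by the component's directory at render
#'   time) and `{PARAMS}` (where rendered parameters are inserted; appended
#'   at the end when absent).
#' @param params list of [param_spec()] objects.
#' @param requirements list with `memory` (string with unit, default
#'   `"1G"`) and `num_cpus` (default 1).
#' @param parallelization optional list with `split_param` (name of the
#'   interval/chunk parameter) and `merge_strategy` (`"concat"`,
#'   `"concat_skip_header"`, or a merge command template containing
#'   `{INPUTS}` and `{OUTPUT}`); both present or both absent.
#' @param version version string recorded in workflow manifests.
#' @return an object of class `component_definition`.
#' @export
component_definition <- function(name, seed_command, params = list(),
                                 requirements = list(), parallelization = NULL,
                                 version = "0.0.1") {
  if (!is_string(name) || !grepl("^[A-Za-z][A-Za-z0-9_]*$", name)) {
    stop(sprintf("invalid component name '%s': must be an identifier", name))
  }
  stopifnot(is_string(seed_command))
  params <- lapply(params, function(p) {
    if (inherits(p, "param_spec")) p
    else do.call(param_spec, p[intersect(names(p), c("name", "role", "required", "default"))])
  })
  pnames <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(pnames)) {
    stop(sprintf("duplicated parameter name(s) in component '%s': %s",
                 name, paste(unique(pnames[duplicated(pnames)]), collapse = ", ")))
  }
  requirements <- list(memory = requirements$memory %||% "1G",
                       num_cpus = as.integer(requirements$num_cpus %||% 1L))
  if (!is.null(parallelization)) {
    sp <- parallelization$split_param
    ms <- parallelization$merge_strategy
    if (is.null(sp) || is.null(ms)) {
      stop(sprintf("component '%s': parallelization requires both split_param and merge_strategy",
                   name))
    }
    if (!sp %in% pnames) {
      stop(sprintf("component '%s': split_param '%s' is not a declared parameter", name, sp))
    }
    if (!ms %in% MERGE_STRATEGIES && !grepl("\\{INPUTS\\}", ms)) {
      stop(sprintf(
        "component '%s': merge_strategy must be %s or a command template with {INPUTS}/{OUTPUT}",
        name, paste(MERGE_STRATEGIES, collapse = "/")))
    }
    parallelization <- list(split_param = sp, merge_strategy = ms)
  }
  structure(list(name = name, seed_command = seed_command, params = params,
                 requirements = requirements, parallelization = parallelization,
                 version = version),
            class = "component_definition")
}

#' @export
print.component_definition <- function(x, ...) {
  cat(sprintf("<component> %s v%s\n  seed: %s\n", x$name, x$version, x$seed_command))
  for (p in x$params) {
    cat(sprintf("  param %s (%s%s%s)\n", p$name, p$role,
                if (p$required) ", required" else "",
                if (!is.null(p$default)) paste0(", default=", p$default) else ""))
  }
  if (!is.null(x$parallelization)) {
    cat(sprintf("  parallelizable over '%s' (merge: %s)\n",
                x$parallelization$split_param, x$parallelization$merge_strategy))
  }
  invisible(x)
}

component_dir <- function(comp) attr(comp, "dir")
component_hash <- function(comp) attr(comp, "definition_hash")

## ---- load / write ---------------------------------------------------------

#' Load a component from its directory
#'
#' Reads and validates `<path>/component.yaml`. The wrapped tool's
#' implementation language is irrelevant: only the declarative definition is
#' interpreted, the seed is executed as a shell command.
#'
#' @param path component directory.
#' @return a validated `component_definition`, carrying the component
#'   directory and an md5 of the definition file as attributes (the latter
#'   feeds workflow manifests and the provenance guard).
#' @export
load_component <- function(path) {
  def_file <- file.path(path, "component.yaml")
  if (!file.exists(def_file)) {
    stop(sprintf("no component definition at '%s'", def_file))
  }
  doc <- tryCatch(ff_yaml_load_file(def_file), error = function(e) {
    stop(sprintf("component definition '%s' is not valid YAML: %s",
                 def_file, conditionMessage(e)))
  })
  required_fields <- c("name", "seed_command")
  missing <- setdiff(required_fields, names(doc))
  if (length(missing)) {
    stop(sprintf("component definition '%s' lacks field(s): %s",
                 def_file, paste(missing, collapse = ", ")))
  }
  comp <- component_definition(
    name = doc$name, seed_command = doc$seed_command,
    params = doc$params %||% list(),
    requirements = doc$requirements %||% list(),
    parallelization = doc$parallelization,
    version = as.character(doc$version %||% "0.0.1")
  )
  attr(comp, "dir") <- normalizePath(path)
  attr(comp, "definition_hash") <- unname(tools::md5sum(def_file))
  comp
}

#' Load every component found under a directory
#'
#' @param path directory whose subdirectories are components, or a character
#'   vector of individual component directories.
#' @return named list `component name -> component_definition` (a registry).
#' @export
load_components <- function(path) {
  dirs <- if (length(path) == 1L && dir.exists(path) &&
              !file.exists(file.path(path, "component.yaml"))) {
    Filter(function(d) file.exists(file.path(d, "component.yaml")),
           list.dirs(path, recursive = FALSE))
  } else path
  comps <- lapply(dirs, load_component)
  stats::setNames(comps, vapply(comps, `[[`, "", "name"))
}

#' Write a component definition file
#'
#' Emits the YAML form read back by [load_component()]; loading and
#' re-writing a definition is stable under field-level equality.
#'
#' @param comp a `component_definition`.
#' @param file destination path (conventionally `<dir>/component.yaml`).
#' @export
write_component_definition <- function(comp, file) {
  stopifnot(inherits(comp, "component_definition"))
  doc <- list(
    name = comp$name, version = comp$version, seed_command = comp$seed_command,
    requirements = comp$requirements,
    params = lapply(comp$params, function(p) Filter(Negate(is.null), unclass(p)))
  )
  if (!is.null(comp$parallelization)) doc$parallelization <- comp$parallelization
  writeLines(yaml::as.yaml(doc, indent.mapping.sequence = TRUE), file)
  invisible(file)
}

## ---- scaffolding -----------------------------------------------------------

#' Scaffold a new component directory
#'
#' Creates the standard component layout — a fillable `component.yaml`, a
#' wrapper stub, an empty `seed/` directory for the wrapped tool's source,
#' a README stub and a `tests/` directory — so a new component can be
#' developed in minutes. The emitted definition file parses as-is.
#'
#' @param name component name (identifier; no path separators).
#' @param dest directory under which `<dest>/<name>/` is created; must not
#'   already contain `<name>` (no clobbering).
#' @return invisibly, a list of the created paths (`root_dir`,
#'   `definition_file`, `wrapper_file`, `seed_dir`, `docs`, `tests_dir`).
#' @export
make_component_template <- function(name, dest = ".") {
  if (!is_string(name) || !grepl("^[A-Za-z][A-Za-z0-9_]*$", name)) {
    stop(sprintf("invalid component name '%s': must be an identifier without path separators",
                 name))
  }
  root <- file.path(dest, name)
  if (dir.exists(root) || file.exists(root)) {
    stop(sprintf("refusing to clobber existing path '%s'", root))
  }
  dir.create(root, recursive = TRUE)
  dir.create(file.path(root, "seed"))
  dir.create(file.path(root, "tests"))
  comp <- component_definition(
    name = name,
    seed_command = sprintf("bash {COMPONENT_DIR}/seed/run.sh"),
    params = list(), version = "0.0.1"
  )
  def_file <- file.path(root, "component.yaml")
  write_component_definition(comp, def_file)
  wrapper <- file.path(root, "wrapper")
  writeLines(c("#!/bin/sh",
               "# executes the rendered command for this component; the engine",
               "# builds the command from component.yaml, so this stub just execs it",
               'exec "$@"'), wrapper)
  Sys.chmod(wrapper, "0755")
  writeLines(c(sprintf("# %s", name), "",
               "Describe the wrapped tool, its parameters and outputs here."),
             file.path(root, "README.md"))
  invisible(list(root_dir = root, definition_file = def_file,
                 wrapper_file = wrapper, seed_dir = file.path(root, "seed"),
                 docs = file.path(root, "README.md"),
                 tests_dir = file.path(root, "tests")))
}

## ---- command rendering ------------------------------------------------------

render_value <- function(v) {
  v <- as.character(v)
  needs_quote <- grepl("[^A-Za-z0-9_./:=,@+-]", v)
  v[needs_quote] <- shQuote(v[needs_quote])
  paste(v, collapse = " ")
}

#' Render the shell command for one task invocation
#'
#' Pure function of its inputs: equal (definition, values, boilerplate)
#' always yield a byte-equal command. Parameters render as `--name value`
#' pairs in declaration order (`flag` parameters as bare `--name`, only when
#' true; unset optional parameters are omitted), inserted at the
#' `{PARAMS}` placeholder of the seed command or appended. A boilerplate —
#' an environment-setup or preprocessing fragment — is prepended and joined
#' with `&&`, so a failing boilerplate aborts the task.
#'
#' @param comp a `component_definition`.
#' @param values named list mapping parameter names to resolved values
#'   (scalars, or vectors/lists for fan-in parameters).
#' @param boilerplate optional command fragment to prepend.
#' @return the command as a single string.
#' @export
build_command <- function(comp, values, boilerplate = NULL) {
  stopifnot(inherits(comp, "component_definition"))
  pnames <- vapply(comp$params, `[[`, "", "name")
  rendered <- character()
  for (p in comp$params) {
    v <- values[[p$name]]
    if (is.null(v) || identical(v, OPTIONAL_PLACEHOLDER)) v <- p$default
    if (is.null(v)) {
      if (isTRUE(p$required)) {
        stop(sprintf("component '%s': required parameter '%s' has no value",
                     comp$name, p$name))
      }
      next
    }
    if (p$role == "flag") {
      if (isTRUE(v) || identical(v, "true")) rendered <- c(rendered, paste0("--", p$name))
    } else {
      rendered <- c(rendered, paste0("--", p$name, " ", render_value(unlist(v))))
    }
  }
  params_str <- paste(rendered, collapse = " ")
  cmd <- comp$seed_command
  if (!is.null(component_dir(comp))) {
    cmd <- gsub("{COMPONENT_DIR}", component_dir(comp), cmd, fixed = TRUE)
  }
  cmd <- if (grepl("{PARAMS}", cmd, fixed = TRUE)) {
    gsub("{PARAMS}", params_str, cmd, fixed = TRUE)
  } else if (nzchar(params_str)) {
    paste(cmd, params_str)
  } else cmd
  if (!is.null(boilerplate) && nzchar(boilerplate)) {
    cmd <- paste(boilerplate, cmd, sep = " && ")
  }
  cmd
}
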