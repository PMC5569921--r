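# init: freeze a configuration plus its component registry into a
# self-contained runnable workflow artifact
#   <out_dir>/<name>/
#     config.yaml        the exact configuration text compiled
#     manifest.yaml      component name -> {version, definition md5}
#     components/        frozen copies of every referenced component
#     sub_workflows/     one concrete configuration per SAMPLES entry
#     run.sh             thin launcher invoking the engine
# Re-running init elsewhere on the same config + components reproduces the
# workflow; the compiler adds no semantics, it freezes them.

copy_tree <- function(from, to) {
  dir.create(to, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(list.files(from, full.names = TRUE), to,
                  recursive = TRUE, copy.mode = TRUE)
  if (!all(ok)) stop(sprintf("failed to copy '%s' into '%s'", from, to))
  invisible(to)
}

#' Initialize (compile) a workflow from a configuration
#'
#' Validates the configuration against the component registry, expands the
#' `SAMPLES` block into per-sample concrete sub-workflows, and writes a
#' self-contained artifact directory embedding the frozen configuration
#' text, a lockfile-style manifest of component versions and definition
#' hashes, copies of the components, and a launcher script. Nothing is
#' written when validation fails. Compiling the same configuration and
#' registry twice yields equal manifests and sub-workflows.
#'
#' @param config_text configuration YAML as a string (read the file first;
#'   the CLI's `init -y file -o name` does).
#' @param components a component registry (named list from
#'   [load_components()]) or a directory of components.
#' @param out_dir directory under which the artifact is created.
#' @param name workflow name; the artifact lands at `<out_dir>/<name>`.
#' @return a `compiled_workflow` (see [load_workflow()]).
#' @export
init_workflow <- function(config_text, components, out_dir = ".", name) {
  stopifnot(is_string(name), grepl("^[A-Za-z][A-Za-z0-9_.-]*$", name))
  if (is.character(components)) components <- load_components(components)
  config <- parse_config(config_text)
  stop_on_errors(validate_config(config, components))
  subs <- expand_samples(config)
  used <- unique(vapply(config$tasks, `[[`, "", "component_name"))
  missing <- setdiff(used, names(components))
  if (length(missing)) {
    abort_validation(sprintf("component(s) not in registry: %s",
                             paste(missing, collapse = ", ")))
  }
  dest <- file.path(out_dir, name)
  if (file.exists(dest)) {
    abort_validation(sprintf("refusing to clobber existing path '%s'", dest))
  }
  # build in a staging directory; move into place only on success
  stage <- tempfile("ffinit")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  writeLines(paste(config_text, collapse = "\n"), file.path(stage, "config.yaml"))
  manifest <- list(
    workflow = name,
    samples = as.list(names(subs)),
    components = lapply(components[used], function(comp) {
      list(version = comp$version, definition_md5 = component_hash(comp))
    })
  )
  writeLines(yaml::as.yaml(manifest, indent.mapping.sequence = TRUE),
             file.path(stage, "manifest.yaml"))
  for (cname in used) {
    copy_tree(component_dir(components[[cname]]),
              file.path(stage, "components", cname))
  }
  dir.create(file.path(stage, "sub_workflows"))
  for (sid in names(subs)) {
    writeLines(config_to_yaml(subs[[sid]]),
               file.path(stage, "sub_workflows", paste0(sid, ".yaml")))
  }
  launcher <- file.path(stage, "run.sh")
  writeLines(c(
    "#!/bin/bash",
    "# single runnable entry point for this workflow artifact",
    'here="$(cd "$(dirname "$0")" && pwd)"',
    paste0("exec Rscript -e 'quit(status = flowforge::main(c(\"run\", ",
           "commandArgs(trailingOnly = TRUE))))' \"$here\" \"$@\"")),
    launcher)
  Sys.chmod(launcher, "0755")
  if (nzchar(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!suppressWarnings(file.rename(stage, dest))) {
    copy_tree(stage, dest)  # staging may sit on another filesystem
  }
  on.exit(NULL)
  unlink(stage, recursive = TRUE)
  load_workflow(dest)
}

#' Load a compiled workflow artifact
#'
#' Reads back an artifact written by [init_workflow()], reloading the frozen
#' configuration and the embedded components. A provenance guard compares
#' each component definition's md5 against the manifest recorded at compile
#' time and refuses to load on mismatch — a changed component means the
#' artifact no longer describes what would run.
#'
#' @param path the artifact directory.
#' @return a `compiled_workflow`: list with `name`, `path`, `config_text`,
#'   `config`, `registry`, `sub_workflows` (named list of concrete
#'   `workflow_config`s, one per sample) and `manifest`.
#' @export
load_workflow <- function(path) {
  for (f in c("config.yaml", "manifest.yaml")) {
    if (!file.exists(file.path(path, f))) {
      abort_validation(sprintf("'%s' is not a workflow artifact (missing %s)", path, f))
    }
  }
  manifest <- ff_yaml_load_file(file.path(path, "manifest.yaml"))
  config_text <- paste(readLines(file.path(path, "config.yaml")), collapse = "\n")
  config <- parse_config(config_text)
  registry <- load_components(file.path(path, "components"))
  for (cname in names(manifest$components)) {
    comp <- registry[[cname]]
    if (is.null(comp)) {
      abort_validation(sprintf("artifact lacks component '%s' named in manifest", cname))
    }
    if (!identical(component_hash(comp), manifest$components[[cname]]$definition_md5)) {
      abort_validation(sprintf(
        "component '%s' changed since compile time (definition hash mismatch); re-run init",
        cname))
    }
  }
  sample_ids <- as.character(unlist(manifest$samples))
  sub_workflows <- lapply(sample_ids, function(sid) {
    parse_config(paste(readLines(file.path(path, "sub_workflows",
                                           paste0(sid, ".yaml"))), collapse = "\n"))
  })
  names(sub_workflows) <- sample_ids
  structure(list(name = manifest$workflow, path = normalizePath(path),
                 config_text = config_text, config = config,
                 registry = registry, sub_workflows = sub_workflows,
                 manifest = manifest),
            class = "compiled_workflow")
}

#' @export
print.compiled_workflow <- function(x, ...) {
  cat(sprintf("<compiled_workflow> %s at %s\n  %d task(s), %d sub-workflow(s), components: %s\n",
              x$name, x$path, length(x$config$tasks), length(x$sub_workflows),
              paste(names(x$manifest$components), collapse = ", ")))
  invisible(x)
}
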