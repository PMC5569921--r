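`%||%` <- function(x, y) if (is.null(x)) y else x

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' MD5 of a character string
#'
#' Hash used for sentinel ledgers and component manifests. Strings are
#' hashed through a temporary file with [tools::md5sum()].
#'
#' @param x character vector; elements are joined with newlines.
#' @return lower-case 32-character md5 string.
#' @keywords internal
hash_string <- function(x) {
  f <- tempfile("ffhash")
  on.exit(unlink(f), add = TRUE)
  writeLines(paste(x, collapse = "\n"), f)
  unname(tools::md5sum(f))
}

# YAML 1.1 implicit typing turns the bare scalars y/n into booleans, which
# silently corrupts single-letter keys like a sweep parameter named `n`.
# These handlers keep y/n literal while true/yes/on and false/no/off still
# resolve to logicals.
FF_YAML_HANDLERS <- list(
  "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
  "bool#no"  = function(x) if (tolower(x) %in% c("false", "no", "off")) FALSE else x
)

ff_yaml_load <- function(text) yaml::yaml.load(text, handlers = FF_YAML_HANDLERS)
ff_yaml_load_file <- function(path) {
  yaml::yaml.load_file(path, handlers = FF_YAML_HANDLERS)
}

abort_validation <- function(message, diagnostics = NULL) {
  stop(structure(
    class = c("flowforge_validation_error", "error", "condition"),
    list(message = message, call = sys.call(-1), diagnostics = diagnostics)
  ))
}

is_validation_error <- function(e) inherits(e, "flowforge_validation_error")

# task section names render as dunder identifiers, e.g. __TASK_1__
TASK_NAME_RE <- "^__[A-Za-z][A-Za-z0-9_]*__$"

RESERVED_SECTION_NAMES <- c("GENERAL", "PIPELINE_INFO", "SHARED", "SAMPLES")

REQUIRED_PLACEHOLDER <- "__REQUIRED__"
OPTIONAL_PLACEHOLDER <- "__OPTIONAL__"
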